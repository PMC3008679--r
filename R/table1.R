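#' Pooled-variance two-sample t from summary statistics
#'
#' Student's two-sample t-test computed from per-group means, standard
#' deviations and sizes, with pooled variance and `n1 + n2 - 2` degrees of
#' freedom; the p-value is two-tailed. When both SDs are zero and the means
#' are equal, t is defined as 0.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list: `t`, `p` (two-tailed), `df`.
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- if (se == 0) {
    if (mean1 == mean2) 0 else stop("zero pooled variance with unequal means")
  } else {
    (mean1 - mean2) / se
  }
  list(t = tval, p = 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE),
       df = df)
}

#' Kruskal-Wallis test on a binary trait from group counts
#'
#' Compares the distribution of a two-category trait (e.g. sex) between two
#' groups given the per-category counts. Observations are expanded from the
#' counts and handed to `stats::kruskal.test`, which assigns midranks and
#' applies the tie correction \eqn{1 - \sum(t^3 - t)/(N^3 - N)}; the p-value
#' comes from the chi-square distribution with 1 df. When every observation
#' falls in one category the test is degenerate and p is defined as 1.
#'
#' @param group_a,group_b integer length-2 vectors of per-category counts.
#' @return list: `h` (tie-corrected statistic), `p`, `df` (= 1).
#' @export
kruskal_wallis_binary <- function(group_a, group_b) {
  stopifnot(length(group_a) == 2, length(group_b) == 2,
            all(group_a >= 0), all(group_b >= 0),
            sum(group_a) + sum(group_b) >= 3, sum(group_a) >= 1,
            sum(group_b) >= 1)
  values <- c(rep(1, group_a[1]), rep(0, group_a[2]),
              rep(1, group_b[1]), rep(0, group_b[2]))
  groups <- factor(c(rep("a", sum(group_a)), rep("b", sum(group_b))))
  if (length(unique(values)) < 2) {
    return(list(h = 0, p = 1, df = 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  list(h = unname(kt$statistic), p = kt$p.value, df = 1L)
}

#' Behavioral/clinical group comparison table
#'
#' Summarizes each clinical score as mean (SD) per group with the pooled
#' two-sample two-tailed t-test, plus a Kruskal-Wallis comparison of the sex
#' split — the standard demographics-and-scores table of a two-group study.
#'
#' @param records data frame with `group` (`"SAD"`/`"HC"`), `sex`, and score
#'   columns.
#' @param scores character vector of numeric columns to compare.
#' @return data frame: variable, per-group mean and sd, t, p.
#' @export
behavioral_table <- function(records,
                             scores = c("age", "education", "lsas_total",
                                        "lsas_fear", "lsas_avoidance", "hamd",
                                        "hama", "stai_t", "stai_s_pre",
                                        "stai_s_post")) {
  stopifnot(all(c("group", "sex") %in% names(records)))
  scores <- intersect(scores, names(records))
  a <- records[records$group == "SAD", , drop = FALSE]
  b <- records[records$group == "HC", , drop = FALSE]
  rows <- lapply(scores, function(sc) {
    tt <- pooled_t_summary(mean(a[[sc]]), stats::sd(a[[sc]]), nrow(a),
                           mean(b[[sc]]), stats::sd(b[[sc]]), nrow(b))
    data.frame(variable = sc,
               sad_mean = mean(a[[sc]]), sad_sd = stats::sd(a[[sc]]),
               hc_mean = mean(b[[sc]]), hc_sd = stats::sd(b[[sc]]),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  kw <- kruskal_wallis_binary(
    c(sum(a$sex == "male"), sum(a$sex == "female")),
    c(sum(b$sex == "male"), sum(b$sex == "female")))
  rows <- c(list(data.frame(variable = "sex_male_fraction",
                            sad_mean = mean(a$sex == "male"), sad_sd = NA,
                            hc_mean = mean(b$sex == "male"), hc_sd = NA,
                            t = NA, p = kw$p, stringsAsFactors = FALSE)),
            rows)
  do.call(rbind, rows)
}
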