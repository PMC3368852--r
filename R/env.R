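#' Site-level environmental summaries
#'
#' Mean, sample standard deviation (n - 1), minimum, maximum and series
#' length per site x variable (temperature in degrees C, light in
#' micromol quanta m^-2 s^-1).
#'
#' @param env Tibble with columns `site`, `variable`, `value` (a
#'   `timestamp` column, if present, is ignored here).
#' @return A tibble with one row per site x variable: `site`, `variable`,
#'   `mean`, `sd`, `min`, `max`, `n`.
#' @export
env_summarise <- function(env) {
  if (nrow(env) == 0) abort("empty environmental series")
  if (any(!is.finite(env$value))) abort("non-finite environmental value")
  summarise(
    group_by(env, .data$site, .data$variable),
    mean = mean(.data$value), sd = sd(.data$value),
    min = min(.data$value), max = max(.data$value), n = n(),
    .groups = "drop")
}

#' Kruskal-Wallis comparison of sites
#'
#' Rank test for differences in an environmental variable between sites,
#' with the usual tie correction (logger data recorded at coarse
#' resolution tie heavily). Wraps [stats::kruskal.test()]; when every
#' observation is identical the statistic is defined as 0 with p = 1.
#'
#' @param env Tibble with columns `site`, `variable`, `value`; each
#'   variable is tested separately across sites.
#' @return A tibble with one row per variable: `variable`, `statistic`
#'   (tie-corrected H), `df`, `p_value`, `n_sites`.
#' @export
env_kruskal <- function(env) {
  vars <- unique(env$variable)
  bind_rows(lapply(vars, function(v) {
    sub <- filter(env, .data$variable == v)
    if (dplyr::n_distinct(sub$site) < 2) abort("need >= 2 sites")
    if (dplyr::n_distinct(sub$value) == 1) {
      return(tibble(variable = v, statistic = 0, df = NA_integer_,
                    p_value = 1, n_sites = dplyr::n_distinct(sub$site)))
    }
    kt <- kruskal.test(sub$value, factor(sub$site))
    tibble(variable = v, statistic = unname(kt$statistic),
           df = unname(kt$parameter), p_value = kt$p.value,
           n_sites = dplyr::n_distinct(sub$site))
  }))
}
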