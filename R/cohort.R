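#' Specification for a synthetic three-group cohort
#'
#' Describes the statistical structure the analysis assumes: three groups
#' (HC, MDD, BD) of equal size, per-tract mean FA with group offsets
#' confined to designated tracts, demographic and clinical covariates with
#' the zero-fill convention for controls, cognition scores, and one
#' designated (group, tract, score) triple whose within-group Pearson
#' correlation is calibrated exactly at the population level.
#'
#' Defaults reproduce the study conditions: n = 30 per group; 54 tracts;
#' FA ~ Normal(0.45, 0.03) with a -0.05 offset in the BD group on the left
#' and right body of the corpus callosum; demographics and cognition score
#' moments taken from the cohort summary statistics (age, gender split,
#' illness duration, depressive episodes, RVP A', five-choice reaction
#' time, IED total errors); target correlation r = 0.387 between left
#' body-of-corpus-callosum FA and the RVP A' score within the BD group.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param tracts character vector of tract names.
#' @param fa_mean baseline tract FA mean.
#' @param fa_sd within-group FA standard deviation (> 0).
#' @param affected named list: tract name -> named numeric of per-group FA
#'   mean offsets, e.g. `list(body_cc_L = c(BD = -0.05))`.
#' @param age,duration,episodes named lists (`HC`, `MDD`, `BD`) of
#'   `c(mean, sd)`; duration and episodes are forced to 0 in HC and
#'   truncated at 0 (episodes also rounded to integers) in patients.
#' @param gender_male_p named numeric of male proportions per group
#'   (gender coded 1 = male, 0 = female).
#' @param scores named list: score name -> named list per group of
#'   `c(mean, sd)`.
#' @param correlation list with elements `group`, `tract`, `score`, `r`
#'   (|r| < 1), or `NULL` for no calibrated correlation.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 30L,
                        tracts = jhu_tract_names(),
                        fa_mean = 0.45, fa_sd = 0.03,
                        affected = list(body_cc_L = c(BD = -0.05),
                                        body_cc_R = c(BD = -0.05)),
                        age = list(HC = c(52.2, 15.3), MDD = c(54.0, 12.4),
                                   BD = c(50.8, 14.9)),
                        gender_male_p = c(HC = 13 / 30, MDD = 11 / 30, BD = 15 / 30),
                        duration = list(HC = c(0, 0), MDD = c(8.6, 9.8),
                                        BD = c(19.7, 14.3)),
                        episodes = list(HC = c(0, 0), MDD = c(3.2, 4.2),
                                        BD = c(8.9, 7.8)),
                        scores = list(
                          RVP_A_prime = list(HC = c(0.93, 0.05),
                                             MDD = c(0.92, 0.06),
                                             BD = c(0.88, 0.05)),
                          RTI_5choice_ms = list(HC = c(284.8, 35.5),
                                                MDD = c(316.5, 48.7),
                                                BD = c(318.7, 51.6)),
                          IED_total_errors = list(HC = c(12.8, 11.0),
                                                  MDD = c(15.3, 14.1),
                                                  BD = c(35.3, 37.9))),
                        correlation = list(group = "BD", tract = "body_cc_L",
                                           score = "RVP_A_prime", r = 0.387),
                        seed = 1L) {
  spec <- structure(list(n_per_group = as.integer(n_per_group), tracts = tracts,
                         fa_mean = fa_mean, fa_sd = fa_sd, affected = affected,
                         age = age, gender_male_p = gender_male_p,
                         duration = duration, episodes = episodes,
                         scores = scores, correlation = correlation,
                         seed = seed),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Benchmark cohort design for power and calibration experiments
#'
#' A [cohort_spec()] variant for Monte-Carlo operating-characteristic
#' runs: a single FA effect (default -0.05 on the left body of the corpus
#' callosum in BD, within-group SD 0.03, n = 30 per group) with *no
#' covariate effects* -- age and gender distributions identical across
#' groups and identical clinical-course distributions for the two patient
#' groups (controls keep the structural zero-fill). This isolates the
#' detection problem from group-covariate collinearity; the methods
#' vignette discusses power under the full demographic design, where the
#' clinical covariates partially encode group membership.
#'
#' @param seed RNG seed.
#' @param offset FA mean shift applied to `tract` in group BD (0 gives the
#'   global null).
#' @param tract affected tract name.
#' @return A `cohort_spec`.
#' @export
benchmark_cohort_spec <- function(seed = 1L, offset = -0.05,
                                  tract = "body_cc_L") {
  affected <- if (offset == 0) list() else
    stats::setNames(list(c(BD = offset)), tract)
  cohort_spec(
    affected = affected, correlation = NULL,
    age = list(HC = c(52.2, 15.3), MDD = c(52.2, 15.3), BD = c(52.2, 15.3)),
    gender_male_p = c(HC = 0.5, MDD = 0.5, BD = 0.5),
    duration = list(HC = c(0, 0), MDD = c(14.2, 12.5), BD = c(14.2, 12.5)),
    episodes = list(HC = c(0, 0), MDD = c(6.1, 6.3), BD = c(6.1, 6.3)),
    seed = seed)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_group < 3L) {
    stop_tendtract("bad_spec", "need at least 3 subjects per group")
  }
  if (spec$fa_sd <= 0) stop_tendtract("bad_spec", "fa_sd must be > 0")
  for (s in names(spec$scores)) {
    sds <- vapply(spec$scores[[s]], `[`, numeric(1), 2)
    if (any(sds <= 0)) stop_tendtract("bad_spec", "score '%s' has a non-positive SD", s)
  }
  for (tr in names(spec$affected)) {
    if (!(tr %in% spec$tracts)) {
      stop_tendtract("bad_spec", "affected tract '%s' is not in the tract list", tr)
    }
  }
  if (!is.null(spec$correlation)) {
    r <- spec$correlation$r
    if (abs(r) >= 1) {
      stop_tendtract("infeasible_correlation",
                     "target correlation r = %.3f is not attainable (|r| must be < 1)", r)
    }
    if (!(spec$correlation$tract %in% spec$tracts) ||
        !(spec$correlation$score %in% names(spec$scores))) {
      stop_tendtract("bad_spec", "correlation target names an unknown tract or score")
    }
  }
  invisible(spec)
}

#' Generate a synthetic cohort table
#'
#' Draws per-subject tract FA as Normal(group tract mean, SD); covariates
#' per the spec with controls' illness duration and episode counts fixed
#' at 0; cognition scores as Normal(group mean, SD) -- except for the
#' designated (group, tract, score) triple, where the score is a linear
#' function of that subject's tract FA plus independent noise with slope
#' and noise variance solved in closed form so the *population*
#' correlation equals the target exactly:
#' score = mu_s + r (sigma_s / sigma_FA) (FA - mu_FA) +
#'         sqrt(1 - r^2) sigma_s eps,  eps ~ N(0, 1).
#' Deterministic for a fixed spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort_table` (see [as_cohort_table()]) with
#'   3 * `n_per_group` rows in group order MDD, BD, HC.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    groups <- c("MDD", "BD", "HC")
    n <- spec$n_per_group
    rows <- list()
    for (g in groups) {
      age <- stats::rnorm(n, spec$age[[g]][1], spec$age[[g]][2])
      gender <- stats::rbinom(n, 1, spec$gender_male_p[[g]])
      if (g == "HC") {
        dur <- rep(0, n); epi <- rep(0, n)
      } else {
        dur <- pmax(0, stats::rnorm(n, spec$duration[[g]][1], spec$duration[[g]][2]))
        epi <- pmax(0, round(stats::rnorm(n, spec$episodes[[g]][1], spec$episodes[[g]][2])))
      }

      fa <- matrix(stats::rnorm(n * length(spec$tracts), spec$fa_mean, spec$fa_sd),
                   n, length(spec$tracts))
      colnames(fa) <- spec$tracts
      for (tr in names(spec$affected)) {
        off <- spec$affected[[tr]]
        if (g %in% names(off)) fa[, tr] <- fa[, tr] + off[[g]]
      }
      fa[] <- pmin(pmax(fa, 0), 1)

      sc <- list()
      for (s in names(spec$scores)) {
        ms <- spec$scores[[s]][[g]]
        co <- spec$correlation
        if (!is.null(co) && co$group == g && co$score == s) {
          off <- spec$affected[[co$tract]]
          off_g <- if (!is.null(off) && g %in% names(off)) off[[g]] else 0
          mu_fa <- spec$fa_mean + off_g
          z <- (fa[, co$tract] - mu_fa) / spec$fa_sd
          sc[[s]] <- ms[1] + co$r * ms[2] * z +
            sqrt(1 - co$r^2) * ms[2] * stats::rnorm(n)
        } else {
          sc[[s]] <- stats::rnorm(n, ms[1], ms[2])
        }
      }

      df <- data.frame(subject_id = sprintf("%s%03d", g, seq_len(n)),
                       group = g, age = age, gender = gender,
                       duration = dur, episodes = epi,
                       stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(sc))
      fa_df <- as.data.frame(fa)
      names(fa_df) <- paste0("fa_", spec$tracts)
      rows[[g]] <- cbind(df, fa_df)
    }
    as_cohort_table(do.call(rbind, c(rows, make.row.names = FALSE)))
  })
}
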