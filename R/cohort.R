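# Virtual preterm-infant cohorts and covariate-adaptive arm assignment.

#' Specification of a virtual cohort
#'
#' Demographic defaults match the closed-loop arm of the feasibility cohort
#' this package emulates: gestational age ~ N(27.0, 2.4) weeks truncated to
#' 22-34, birth weight ~ N(962, 164) g truncated below the 1200 g
#' eligibility bound, maintenance dextrose ~ N(8.4, 1.5) mg/kg/min. Baseline
#' insulin sensitivity is log-normal across infants with median one quarter
#' of a term reference of 2e-3 min^-1 per mU/L and between-infant CV 50%
#' (extreme prematurity); within-infant temporal variability is a log-OU
#' process (see [evolve_sensitivity()]) with a 24-h diffusion CV of 1.0 and
#' 6-h reversion, i.e. a stationary within-infant CV of about 30%. Baseline
#' sensor glucose at 48 h (used when a run starts mid-protocol) is
#' log-normal with median 8 mmol/L.
#'
#' @param n number of infants (>= 0).
#' @param ga_mean,ga_sd gestational age distribution, weeks.
#' @param ga_min,ga_max truncation bounds for gestational age, weeks.
#' @param bw_mean,bw_sd birth weight distribution, g.
#' @param bw_min,bw_max truncation bounds for birth weight, g (eligibility
#'   requires `bw_max <= 1200`).
#' @param si_median median baseline insulin sensitivity, 1/min per mU/L.
#' @param si_cv between-infant CV of baseline sensitivity.
#' @param si_volatility within-infant 24-h diffusion CV of the sensitivity
#'   multiplier.
#' @param si_reversion_h sensitivity mean-reversion time, hours.
#' @param dex_mean,dex_sd maintenance dextrose distribution, mg/kg/min.
#' @param trophic_prob probability an infant receives trophic feeds.
#' @param trophic_carb carbohydrate flux of trophic feeds, mg/kg/min.
#' @param baseline_sg_median,baseline_sg_sdlog log-normal parameters of the
#'   48-h baseline sensor glucose, mmol/L.
#' @param seed integer seed making sampling reproducible.
#' @return list with class `cohort_spec`.
#' @export
cohort_spec <- function(n, ga_mean = 27.0, ga_sd = 2.4,
                        ga_min = 22, ga_max = 34,
                        bw_mean = 962, bw_sd = 164,
                        bw_min = 400, bw_max = 1200,
                        si_median = 5e-4, si_cv = 0.5,
                        si_volatility = 1.0, si_reversion_h = 6,
                        dex_mean = 8.4, dex_sd = 1.5,
                        trophic_prob = 0.4, trophic_carb = 0.3,
                        baseline_sg_median = 8.0, baseline_sg_sdlog = 0.2,
                        seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (ga_sd < 0 || bw_sd < 0 || dex_sd < 0) stop("sds must be >= 0")
  if (bw_max > 1200) stop("eligibility requires birth weight < 1200 g")
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

# Truncated-normal draws by resampling until inside (lo, hi).
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean <= lo || mean >= hi) stop("degenerate mean outside bounds")
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > lo & draw < hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Sample a virtual preterm cohort
#'
#' Deterministic given `spec$seed`. Birth weights and gestational ages are
#' truncated-normal (resampled until inside bounds); every infant satisfies
#' the < 1200 g eligibility bound by construction.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per infant: demographics, physiology
#'   parameters and nutrition schedule.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  if (n == 0) {
    return(data.frame(id = character(0), ga_weeks = numeric(0),
                      bw_g = numeric(0), sex = character(0),
                      si_base = numeric(0), si_volatility = numeric(0),
                      si_reversion_h = numeric(0), egp0 = numeric(0),
                      maintenance_dextrose = numeric(0),
                      trophic_carb = numeric(0), protein_g_kg_d = numeric(0),
                      lipid_g_kg_d = numeric(0), baseline_sg = numeric(0),
                      stringsAsFactors = FALSE))
  }
  set.seed(spec$seed)
  ga <- .rtruncnorm(n, spec$ga_mean, spec$ga_sd, spec$ga_min, spec$ga_max)
  bw <- .rtruncnorm(n, spec$bw_mean, spec$bw_sd, spec$bw_min, spec$bw_max)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sdlog <- sqrt(log(1 + spec$si_cv^2))
  si <- spec$si_median * exp(stats::rnorm(n, 0, sdlog))
  dex <- .rtruncnorm(n, spec$dex_mean, spec$dex_sd, 2, 16)
  trophic <- ifelse(stats::runif(n) < spec$trophic_prob, spec$trophic_carb, 0)
  baseline <- spec$baseline_sg_median *
    exp(stats::rnorm(n, 0, spec$baseline_sg_sdlog))
  data.frame(
    id = sprintf("inf%02d", seq_len(n)),
    ga_weeks = round(ga, 1),
    bw_g = round(bw),
    sex = sex,
    si_base = si,
    si_volatility = spec$si_volatility,
    si_reversion_h = spec$si_reversion_h,
    egp0 = 4,
    maintenance_dextrose = round(dex, 2),
    trophic_carb = trophic,
    protein_g_kg_d = round(.rtruncnorm(n, 3.2, 0.7, 1, 5), 1),
    lipid_g_kg_d = round(.rtruncnorm(n, 1.8, 0.5, 0.4, 3.5), 1),
    baseline_sg = round(baseline, 1),
    stringsAsFactors = FALSE
  )
}

#' Assign arms by Pocock-Simon minimisation
#'
#' Sequentially assigns each infant to the arm minimising the sum, over the
#' gestational-age and birth-weight stratification factors, of the
#' post-assignment absolute between-arm count imbalance in the infant's
#' category. Ties are broken by a seeded coin flip; the first infant is
#' randomised. Default cut-points form clinically conventional strata:
#' gestational age <26 / 26-28 / >28 weeks, birth weight <750 / 750-1000 /
#' >=1000 g.
#'
#' @param profiles cohort data.frame from [sample_cohort()].
#' @param ga_cuts,bw_cuts internal cut-points (category boundaries) for the
#'   two factors.
#' @param seed integer seed for the randomised tie-breaks.
#' @param p_minimising probability of assigning to the minimising arm when
#'   the imbalance sums differ (1 = deterministic Taves-style minimisation).
#' @return data.frame with columns `id`, `arm` (`closed_loop` / `control`),
#'   `stratum_ga`, `stratum_bw`.
#' @export
assign_arms_minimisation <- function(profiles, ga_cuts = c(26, 28),
                                     bw_cuts = c(750, 1000), seed = 1L,
                                     p_minimising = 1.0) {
  if (nrow(profiles) == 0) stop("at least one profile is required")
  set.seed(seed)
  arms <- c("closed_loop", "control")
  cat_ga <- findInterval(profiles$ga_weeks, ga_cuts) + 1L
  cat_bw <- findInterval(profiles$bw_g, bw_cuts) + 1L
  n_ga <- length(ga_cuts) + 1L
  n_bw <- length(bw_cuts) + 1L
  counts_ga <- matrix(0L, n_ga, 2) # categories x arms
  counts_bw <- matrix(0L, n_bw, 2)
  assigned <- character(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    g <- cat_ga[i]; b <- cat_bw[i]
    score <- vapply(1:2, function(a) {
      cg <- counts_ga[g, ]; cg[a] <- cg[a] + 1L
      cb <- counts_bw[b, ]; cb[a] <- cb[a] + 1L
      abs(cg[1] - cg[2]) + abs(cb[1] - cb[2])
    }, numeric(1))
    pick <- if (score[1] == score[2]) {
      sample(1:2, 1)
    } else if (stats::runif(1) < p_minimising) {
      which.min(score)
    } else {
      which.max(score)
    }
    assigned[i] <- arms[pick]
    counts_ga[g, pick] <- counts_ga[g, pick] + 1L
    counts_bw[b, pick] <- counts_bw[b, pick] + 1L
  }
  data.frame(id = profiles$id, arm = assigned,
             stratum_ga = cat_ga, stratum_bw = cat_bw,
             stringsAsFactors = FALSE)
}

#' Per-category arm imbalance of an assignment
#'
#' Audit helper: maximum absolute between-arm count difference within any
#' single category of either stratification factor.
#'
#' @param assignment data.frame from [assign_arms_minimisation()].
#' @return integer, the worst per-category imbalance.
#' @export
assignment_imbalance <- function(assignment) {
  worst <- 0L
  for (f in c("stratum_ga", "stratum_bw")) {
    tab <- table(assignment[[f]], factor(assignment$arm,
                                         c("closed_loop", "control")))
    worst <- max(worst, max(abs(tab[, 1] - tab[, 2])))
  }
  as.integer(worst)
}

#' Write / read a cohort with its assignment as CSV
#'
#' @param profiles cohort data.frame.
#' @param assignment data.frame from [assign_arms_minimisation()] or NULL.
#' @param path CSV file path.
#' @return (`read_cohort`) the cohort data.frame, arm columns included when
#'   present.
#' @export
write_cohort <- function(profiles, assignment = NULL, path) {
  out <- profiles
  if (!is.null(assignment)) out <- merge(out, assignment, by = "id", sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
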