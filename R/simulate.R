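#' Reference marginal moments for a metastatic colorectal cancer QoL cohort
#'
#' Published marginal means and standard deviations of the 15 QLQ-C30 scale
#' scores in 1905 questionnaires from 473 patients with metastatic
#' colorectal cancer on maintenance treatment or observation. These are the
#' default calibration targets of [generate_cohort()] and the default
#' covariate moments of [generate_from_linear_model()].
#'
#' @return Data frame with columns `scale`, `mean`, `sd`.
#' @export
reference_cohort_moments <- function() {
  data.frame(
    scale = c("physical", "role", "emotional", "cognitive", "social",
              "global_health", "fatigue", "nausea_vomiting", "pain",
              "dyspnea", "insomnia", "appetite_loss", "constipation",
              "diarrhea", "financial"),
    mean = c(82.681, 76.947, 85.744, 89.221, 86.177, 74.711, 24.205,
             4.234, 13.508, 10.866, 15.083, 9.729, 6.824, 10.569, 6.229),
    sd = c(17.195, 24.218, 15.829, 15.294, 18.718, 17.464, 20.059,
           11.286, 20.705, 19.061, 22.297, 19.651, 15.917, 19.363, 15.978),
    stringsAsFactors = FALSE
  )
}

#' Reference EQ-5D-3L domain level frequencies
#'
#' Published marginal level frequencies (levels 1/2/3) of the five
#' EQ-5D-3L domains in the same cohort; used to place the domain cutpoints
#' of [generate_cohort()] by moment matching.
#'
#' @return 5 x 3 matrix of probabilities (rows: domains; rows sum to 1).
#' @export
reference_eq5d_frequencies <- function() {
  f <- rbind(
    mobility           = c(57.9, 41.8, 0.3),
    self_care          = c(93.4,  6.1, 0.4),
    usual_activities   = c(57.5, 38.5, 3.9),
    pain_discomfort    = c(60.2, 38.4, 1.4),
    anxiety_depression = c(77.2, 21.8, 1.0)
  )
  f <- f / rowSums(f)
  colnames(f) <- c("1", "2", "3")
  f
}

#' Specify a synthetic paired-questionnaire cohort
#'
#' Collects the knobs of the latent-trait generator. A single latent health
#' trait per patient (SD `sd_between`) plus a per-visit deviation
#' (SD `sd_within`) drives both instruments: QLQ-C30 items arise by cutting
#' the trait plus item noise at per-scale calibrated thresholds, EQ-5D
#' domain levels by cutting it at thresholds placed to match the reference
#' level frequencies. This induces the within-patient clustering and the
#' cross-instrument correlation the mapping models assume.
#'
#' @param n_patients Number of patients.
#' @param n_rows Total number of complete paired records (visits are spread
#'   over patients as evenly as possible, so the total is exact).
#' @param n_incomplete Additional records whose QLQ-C30 has item-level gaps
#'   (functional scales remain computable under the half-completion rule).
#' @param sd_between,sd_within Latent-trait SD between patients and of the
#'   per-visit deviation.
#' @param item_noise_sd SD of the item-specific latent noise.
#' @param utility_noise_sd SD of the domain-specific latent noise for the
#'   EQ-5D domains.
#' @param score_moments Calibration targets for the 15 scale scores
#'   (defaults to [reference_cohort_moments()]).
#' @param eq5d_frequencies 5 x 3 matrix of domain level frequencies
#'   (defaults to [reference_eq5d_frequencies()]).
#' @param value_set Tariff used to compute observed utilities (name passed
#'   to [load_value_set()], or an `eq5d_value_set`).
#' @param ceiling_mass Probability that a record is forced to full health
#'   (state 1-1-1-1-1, best item responses). The default 0 leaves the
#'   ceiling at utility 1 to arise from the correlated domain levels.
#' @param extra_negative_rate Probability that a record's latent trait is
#'   shifted into the deep-illness tail, producing (mostly) states worse
#'   than dead. Default 0.002.
#' @param item_missing_rate Per-item deletion probability for the
#'   incomplete records (must be in `[0, 0.5)`).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 473L, n_rows = 1905L,
                        n_incomplete = 120L,
                        sd_between = 1, sd_within = 0.5,
                        item_noise_sd = 1, utility_noise_sd = 0.7,
                        score_moments = reference_cohort_moments(),
                        eq5d_frequencies = reference_eq5d_frequencies(),
                        value_set = "NL",
                        ceiling_mass = 0, extra_negative_rate = 0.002,
                        item_missing_rate = 0.2) {
  stopifnot(n_patients >= 1, n_rows >= n_patients, n_incomplete >= 0,
            sd_between >= 0, sd_within >= 0, item_noise_sd >= 0,
            utility_noise_sd >= 0)
  if (ceiling_mass < 0 || ceiling_mass > 1 ||
      extra_negative_rate < 0 || extra_negative_rate > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (item_missing_rate < 0 || item_missing_rate >= 0.5)
    stop("item_missing_rate must lie in [0, 0.5)", call. = FALSE)
  if (any(score_moments$mean < 0 | score_moments$mean > 100))
    stop("infeasible target: scale means must lie in [0, 100]", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients), n_rows = as.integer(n_rows),
    n_incomplete = as.integer(n_incomplete),
    sd_between = sd_between, sd_within = sd_within,
    item_noise_sd = item_noise_sd, utility_noise_sd = utility_noise_sd,
    score_moments = score_moments, eq5d_frequencies = eq5d_frequencies,
    value_set = value_set, ceiling_mass = ceiling_mass,
    extra_negative_rate = extra_negative_rate,
    item_missing_rate = item_missing_rate
  ), class = "cohort_spec")
}

# Deterministic sub-seed for a named stage, so stages are independently
# reproducible from one master seed. Kept below 2^31.
substream_seed <- function(seed, stage) {
  k <- match(stage, c("cohort", "missingness", "folds", "psa", "arms"))
  if (is.na(k)) stop("unknown seed substream '", stage, "'")
  as.integer((as.double(seed) + k * 1000003) %% 2147483629)
}

# Marginal mean of an ordinal item cut from N(0, v_marg) at thresholds tau.
ordinal_mean <- function(tau, v_marg) {
  1 + sum(1 - stats::pnorm(tau / sqrt(max(v_marg, 1e-12))))
}

# Mean and SD of the scale raw score (mean of n_items exchangeable items
# sharing the latent trait h ~ N(0, v_h); item = cut(h + e, tau),
# e ~ N(0, v_e)). The h-integral is evaluated on a fixed quadrature grid.
raw_score_moments <- function(tau, n_items, n_levels, v_h, v_e) {
  if (v_h <= 0) {
    p_gt <- 1 - stats::pnorm(tau / sqrt(max(v_e, 1e-12)))
    m <- 1 + sum(p_gt)
    p <- c(1, p_gt) - c(p_gt, 0)  # p_1..p_L
    v <- sum((1:n_levels)^2 * p) - m^2
    return(c(mean = m, sd = sqrt(max(v, 0) / n_items)))
  }
  sh <- sqrt(v_h)
  nodes <- seq(-6, 6, length.out = 241) * sh
  w <- stats::dnorm(nodes, 0, sh)
  w <- w / sum(w)
  se <- sqrt(max(v_e, 1e-12))
  p_gt <- sapply(tau, function(t) 1 - stats::pnorm((t - nodes) / se))  # grid x thr
  cond_mean <- 1 + rowSums(p_gt)
  upper <- cbind(1, p_gt)            # P(item >= l), l = 1..L
  p_lev <- upper - cbind(p_gt, 0)    # P(item = l)
  cond_e2 <- p_lev %*% (1:n_levels)^2
  cond_var <- pmax(cond_e2 - cond_mean^2, 0)
  m <- sum(w * cond_mean)
  v_between <- sum(w * (cond_mean - m)^2)
  v_within <- sum(w * cond_var) / n_items
  c(mean = m, sd = sqrt(v_between + v_within))
}

# Solve for equally spaced thresholds (location alpha, spacing delta) so
# that the scale raw-score mean and SD match their targets.
calibrate_scale <- function(target_mean, target_sd, n_items, n_levels,
                            v_h, v_e, scale_name) {
  v_marg <- v_h + v_e
  steps <- seq_len(n_levels - 1) - 1
  solve_alpha <- function(delta) {
    f <- function(a) ordinal_mean(a + delta * steps, v_marg) - target_mean
    lim <- 10 * sqrt(v_marg) + delta * (n_levels - 1)
    stats::uniroot(f, c(-lim, lim), tol = 1e-10)$root
  }
  sd_at <- function(delta) {
    a <- solve_alpha(delta)
    raw_score_moments(a + delta * steps, n_items, n_levels, v_h, v_e)[["sd"]] -
      target_sd
  }
  lo <- 1e-3; hi <- 8
  f_lo <- sd_at(lo); f_hi <- sd_at(hi)
  if (f_lo * f_hi > 0) {
    if (abs(f_lo) < abs(f_hi)) {
      delta <- lo
    } else delta <- hi
    if (min(abs(f_lo), abs(f_hi)) > 0.25 * target_sd)
      stop("infeasible scale moment targets for scale '", scale_name, "'",
           call. = FALSE)
  } else {
    delta <- stats::uniroot(sd_at, c(lo, hi), tol = 1e-8)$root
  }
  alpha <- solve_alpha(delta)
  alpha + delta * steps
}

# Thresholds for the calibrated targets of a spec: named list scale -> tau.
calibrate_spec <- function(spec) {
  tab <- qlq_scales()
  v_h <- spec$sd_between^2 + spec$sd_within^2
  v_e <- spec$item_noise_sd^2
  mom <- spec$score_moments
  out <- list()
  for (i in seq_len(nrow(tab))) {
    sc <- tab$scale[i]
    m <- mom$mean[mom$scale == sc]
    s <- mom$sd[mom$scale == sc]
    if (length(m) != 1)
      stop("score_moments must contain scale '", sc, "'", call. = FALSE)
    rng <- tab$range[i]
    rs_mean <- if (tab$type[i] == "functional") 1 + rng * (1 - m / 100)
               else 1 + rng * m / 100
    rs_sd <- s * rng / 100
    out[[sc]] <- calibrate_scale(rs_mean, rs_sd, length(tab$items[[i]]),
                                 rng + 1L, v_h, v_e, sc)
  }
  out
}

balanced_visits <- function(n_patients, n_rows) {
  base <- n_rows %/% n_patients
  extra <- n_rows - base * n_patients
  counts <- rep(base, n_patients)
  if (extra > 0) counts[seq_len(extra)] <- base + 1
  counts
}

resolve_value_set <- function(vs) {
  if (inherits(vs, "eq5d_value_set")) vs else load_value_set(vs)
}

draw_rows <- function(spec, patient_ids, visit_ids, h, tau_items, tau_eq5d,
                      vs) {
  n <- length(h)
  tab <- qlq_scales()
  neg <- stats::runif(n) < spec$extra_negative_rate
  ceilr <- stats::runif(n) < spec$ceiling_mass
  v_h <- spec$sd_between^2 + spec$sd_within^2
  h_eff <- h - neg * 3 * sqrt(max(v_h, 1e-12))

  out <- data.frame(patient_id = patient_ids, visit = visit_ids)
  # QLQ items: q1..q28 oriented so higher latent health -> lower item level
  for (i in seq_len(nrow(tab))) {
    sc <- tab$scale[i]
    orient <- if (sc == "global_health") 1 else -1
    tau <- tau_items[[sc]]
    for (it in tab$items[[i]]) {
      x <- orient * h_eff + stats::rnorm(n, 0, spec$item_noise_sd)
      lev <- 1L + rowSums(outer(x, tau, ">"))
      out[[it]] <- as.integer(lev)
    }
  }
  # EQ-5D domains: higher latent health -> lower level
  for (d in eq5d_domains()) {
    x <- -h_eff + stats::rnorm(n, 0, spec$utility_noise_sd)
    out[[d]] <- as.integer(1L + (x > tau_eq5d[[d]][1]) + (x > tau_eq5d[[d]][2]))
  }
  if (any(ceilr)) {
    for (it in paste0("q", 1:28)) out[[it]][ceilr] <- 1L
    for (it in paste0("q", 29:30)) out[[it]][ceilr] <- 7L
    for (d in eq5d_domains()) out[[d]][ceilr] <- 1L
  }
  out <- out[, c("patient_id", "visit", qlq_item_names(), eq5d_domains())]
  out$utility <- as.numeric(eq5d_utility(out, vs))
  out
}

#' Generate a synthetic paired QLQ-C30 / EQ-5D-3L panel cohort
#'
#' Draws a cohort according to a [cohort_spec()]: per patient a latent
#' health trait, per visit the trait plus noise, mapped through calibrated
#' ordinal cutpoints to the 30 QLQ-C30 items and the 5 EQ-5D-3L domains.
#' Scale-score marginal moments match the spec's calibration targets in
#' expectation; observed utilities are the value-set score of the generated
#' domain levels, so they are consistent with the response by construction.
#' The same seed reproduces the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `visit`, items `q1`..`q30`, the
#'   five EQ-5D domain columns, `utility` and a logical `complete` flag
#'   (`FALSE` for the `n_incomplete` records with item gaps). Attribute
#'   `value_set` records the tariff name.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  vs <- resolve_value_set(spec$value_set)
  tau_items <- calibrate_spec(spec)
  v_d <- spec$sd_between^2 + spec$sd_within^2 + spec$utility_noise_sd^2
  freq <- spec$eq5d_frequencies
  tau_eq5d <- lapply(eq5d_domains(), function(d) {
    p <- freq[d, ]
    stats::qnorm(cumsum(p)[1:2]) * sqrt(max(v_d, 1e-12))
  })
  names(tau_eq5d) <- eq5d_domains()

  set.seed(substream_seed(seed, "cohort"))
  h_pat <- stats::rnorm(spec$n_patients, 0, spec$sd_between)

  counts <- balanced_visits(spec$n_patients, spec$n_rows)
  pid <- rep(seq_len(spec$n_patients), counts)
  visit <- unlist(lapply(counts, seq_len), use.names = FALSE)
  h <- h_pat[pid] + stats::rnorm(length(pid), 0, spec$sd_within)
  complete_rows <- draw_rows(spec, pid, visit, h, tau_items, tau_eq5d, vs)
  complete_rows$complete <- TRUE

  if (spec$n_incomplete > 0) {
    ipid <- sample(seq_len(spec$n_patients), spec$n_incomplete, replace = TRUE)
    ivisit <- 100L + seq_len(spec$n_incomplete)
    ih <- h_pat[ipid] + stats::rnorm(spec$n_incomplete, 0, spec$sd_within)
    inc <- draw_rows(spec, ipid, ivisit, ih, tau_items, tau_eq5d, vs)
    inc <- delete_items(inc, spec$item_missing_rate, force_missing = TRUE)
    inc$complete <- FALSE
    complete_rows <- rbind(complete_rows, inc)
  }
  attr(complete_rows, "value_set") <- vs$name
  attr(complete_rows, "spec") <- spec
  complete_rows
}

# Item-level MCAR deletion constrained so that every functional scale
# keeps at least half of its items (half-completion rule stays satisfiable).
delete_items <- function(rows, rate, force_missing = FALSE) {
  items <- qlq_item_names()
  tab <- qlq_scales()
  fun_tab <- tab[tab$type == "functional", ]
  n <- nrow(rows)
  miss <- matrix(stats::runif(n * 30) < rate, nrow = n)
  colnames(miss) <- items
  for (i in seq_len(nrow(fun_tab))) {
    its <- fun_tab$items[[i]]
    allowed <- length(its) - ceiling(length(its) / 2)
    for (r in seq_len(n)) {
      del <- which(miss[r, its])
      if (length(del) > allowed) {
        keep_del <- if (allowed > 0) sample(del, allowed) else integer(0)
        miss[r, its] <- FALSE
        miss[r, its[keep_del]] <- TRUE
      }
    }
  }
  if (force_missing) {
    none <- rowSums(miss) == 0
    if (any(none)) {
      singles <- c("q8", "q11", "q13", "q16", "q17", "q28")
      pick <- sample(singles, sum(none), replace = TRUE)
      for (j in seq_along(which(none))) miss[which(none)[j], pick[j]] <- TRUE
    }
  }
  for (it in items) rows[[it]][miss[, it]] <- NA_integer_
  rows
}

#' Inject item-level missingness into a cohort
#'
#' Deletes QLQ-C30 items completely at random at the given per-item rate,
#' subject to the constraint that every functional scale retains at least
#' half of its items (so functional scale scores remain computable under
#' the half-completion rule). The `complete` flag is updated.
#'
#' @param cohort Cohort data frame (as from [generate_cohort()]).
#' @param rate Per-item deletion probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return The cohort with item gaps.
#' @export
inject_item_missingness <- function(cohort, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5)
    stop("rate must lie in [0, 0.5)", call. = FALSE)
  if (rate == 0) return(cohort)
  set.seed(substream_seed(seed, "missingness"))
  out <- delete_items(cohort, rate)
  out$complete <- rowSums(is.na(out[, qlq_item_names()])) == 0
  out
}
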