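#' Attenuation of a Pearson correlation under Likert discretization
#'
#' A standard-normal latent discretized at equiprobable cutpoints into `L`
#' ordered categories correlates `A(L) < 1` with the latent; the correlation
#' of two discretized bivariate-normal variables is attenuated by
#' approximately `A(L)^2` (exactly so in the linear approximation; the
#' generator uses the exact map [likert_corr()] instead).
#'
#' @param L Number of Likert levels.
#' @return Scalar attenuation `A(L)` in (0, 1).
#' @export
likert_attenuation <- function(L) {
  stopifnot(L >= 2L)
  cut <- stats::qnorm(seq_len(L - 1L) / L)
  dens <- c(0, stats::dnorm(cut), 0)            # phi at -Inf, cuts, Inf
  cov_xd <- sum(seq_len(L) * (dens[seq_len(L)] - dens[seq_len(L) + 1L]))
  var_d <- mean((seq_len(L))^2) - mean(seq_len(L))^2
  cov_xd / sqrt(var_d)
}

#' Post-discretization correlation of two Likert items
#'
#' Exact Pearson correlation of two standard-normal latents with correlation
#' `rho`, each discretized at equiprobable cutpoints into `L` levels.
#' Evaluated by one-dimensional Gauss-Legendre-free quadrature:
#' `E[D1 D2] = E[ d(X) * E[d(Y) | X] ]` with the inner conditional
#' expectation in closed form. [calibrate_latent_corr()] inverts this map so
#' the generator's realized item correlations land on their targets.
#'
#' @param rho Latent (continuous-scale) correlation in (-1, 1).
#' @param L Number of Likert levels.
#' @param n_nodes Quadrature grid size.
#' @return The correlation of the discretized pair.
#' @export
likert_corr <- function(rho, L, n_nodes = 400L) {
  stopifnot(abs(rho) < 1)
  cuts <- stats::qnorm(seq_len(L - 1L) / L)
  lv <- seq_len(L)
  mu_d <- mean(lv)
  var_d <- mean(lv^2) - mu_d^2
  # trapezoid over x in [-8, 8]
  x <- seq(-8, 8, length.out = n_nodes)
  w <- stats::dnorm(x) * (x[2L] - x[1L])
  dx <- findInterval(x, cuts) + 1L
  s <- sqrt(1 - rho^2)
  cdf <- vapply(cuts, function(cc) stats::pnorm((cc - rho * x) / s),
                numeric(length(x)))
  probs <- cbind(cdf, 1)
  probs[, -1L] <- probs[, -1L] - cdf
  e_dy <- as.numeric(probs %*% lv)
  e_dd <- sum(w * dx * e_dy)
  (e_dd - mu_d^2) / var_d
}

#' @rdname likert_corr
#' @param target Desired post-discretization correlation.
#' @export
calibrate_latent_corr <- function(target, L) {
  if (target == 0) return(0)
  if (abs(target) >= likert_corr(0.995, L))
    stop("correlation target ", target, " not attainable after ", L,
         "-level discretization")
  stats::uniroot(function(r) likert_corr(r, L) - target,
                 interval = c(-0.995, 0.995), tol = 1e-6)$root
}

#' Configure a synthetic survey
#'
#' Builds the configuration for [generate_dataset()]. The defaults emulate
#' the study conditions the pipeline is designed for: 1020 respondents; four
#' Likert scales totalling 85 items with 4 + 5 + 3 + 4 planted item clusters;
#' within-cluster correlations just above the per-scale quality floors the
#' factor-selection stage uses (0.7 / 0.6 / 0.5 / 0.6) and weak
#' between-cluster correlation; a dose in 0..5 driven by three of the
#' sixteen latent factors plus noise, yielding a cohort mean dose near 1.5;
#' demographic variables with cohort marginals resembling a Deep-South adult
#' sample; and one planted subgroup (12% of respondents) that is compact in
#' factor space, has one factor splitting its doses to the extremes, and is
#' enriched for older and Republican respondents.
#'
#' @param n_respondents Cohort size.
#' @param scales List of per-scale specs: `scale_id`, `prefix`, `n_items`,
#'   `n_clusters`, `within_pcc`, `between_pcc` (post-discretization targets),
#'   `likert` (c(min, max)), `reverse_fraction`.
#' @param dose_model List: `intercept`, `coefficients` (named by factor id),
#'   `noise_sd`.
#' @param demographics Named list: variable -> named probability vector over
#'   categories (each summing to 1).
#' @param planted_subgroups List of subgroup specs: `fraction`, `center`
#'   (scalar or named vector over factor ids), `spread`, `driver` (factor
#'   id), `driver_gap` (half-distance between the driver factor's two modes
#'   within the subgroup; members above the subgroup median of the driver
#'   get dose 5, the rest dose 0, so a positive gap makes the split cleanly
#'   observable in the item responses), `radial_sd` (scatter of the members'
#'   overall profile intensity along the subgroup's own offset direction),
#'   `strength` in [0, 1], optional `demographics` overrides.
#' @param seed Integer seed; the generator is fully determined by it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_respondents = 1020L,
                             scales = default_scale_specs(),
                             dose_model = default_dose_model(),
                             demographics = default_demographics(),
                             planted_subgroups = default_subgroups(),
                             seed = 42L) {
  for (s in scales) {
    stopifnot(!is.null(s$scale_id), s$n_items >= s$n_clusters,
              s$likert[2L] > s$likert[1L])
    if (!(s$within_pcc > s$between_pcc))
      stop("config error: scale '", s$scale_id,
           "': within_pcc must exceed between_pcc")
    if (s$reverse_fraction < 0 || s$reverse_fraction > 1)
      stop("config error: reverse_fraction outside [0, 1]")
  }
  for (g in planted_subgroups) {
    if (g$fraction < 0 || g$fraction > 1)
      stop("config error: subgroup fraction outside [0, 1]")
    if (!is.null(g$strength) && (g$strength < 0 || g$strength > 1))
      stop("config error: subgroup strength outside [0, 1]")
  }
  for (v in names(demographics)) {
    p <- demographics[[v]]
    if (abs(sum(p) - 1) > 1e-6)
      stop("config error: demographic '", v, "' probabilities must sum to 1")
  }
  structure(
    list(n_respondents = as.integer(n_respondents), scales = scales,
         dose_model = dose_model, demographics = demographics,
         planted_subgroups = planted_subgroups, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_scale_specs <- function() list(
  list(scale_id = "CoVaH", prefix = "C", n_items = 25L, n_clusters = 4L,
       within_pcc = 0.75, between_pcc = 0.15, likert = c(1L, 5L),
       reverse_fraction = 0.2),
  list(scale_id = "T-DiG", prefix = "D", n_items = 30L, n_clusters = 5L,
       within_pcc = 0.65, between_pcc = 0.15, likert = c(1L, 5L),
       reverse_fraction = 0.2),
  list(scale_id = "TRUST-Ph", prefix = "P", n_items = 15L, n_clusters = 3L,
       within_pcc = 0.55, between_pcc = 0.15, likert = c(1L, 5L),
       reverse_fraction = 0.2),
  list(scale_id = "TiPHA", prefix = "G", n_items = 15L, n_clusters = 4L,
       within_pcc = 0.65, between_pcc = 0.15, likert = c(1L, 4L),
       reverse_fraction = 0.2))

#' @rdname synthetic_config
#' @export
default_dose_model <- function() list(
  intercept = 1.3,
  coefficients = c("C-c1" = -0.9, "C-c2" = -0.6, "C-c4" = -0.5),
  noise_sd = 0.8)

#' @rdname synthetic_config
#' @export
default_demographics <- function() list(
  sex = c(Male = 0.30, Female = 0.70),
  age_group = c("18-34" = 0.27, "35-54" = 0.39, "55-64" = 0.16, "65+" = 0.18),
  race = c(White = 0.70, Black = 0.22, Other = 0.08),
  political_affiliation = c(Republican = 0.42, Democrat = 0.20,
                            Independent = 0.24, Other = 0.14),
  flu_shot = c(Yes = 0.40, No = 0.60))

#' @rdname synthetic_config
#' @export
default_subgroups <- function() list(
  list(fraction = 0.12, center = 1.5, spread = 0.4, driver = "C-c1",
       driver_gap = 0.8, strength = 1,
       demographics = list(
         age_group = c("18-34" = 0.10, "35-54" = 0.20, "55-64" = 0.25,
                       "65+" = 0.45),
         political_affiliation = c(Republican = 0.75, Democrat = 0.05,
                                   Independent = 0.12, Other = 0.08))))

#' Benchmark configuration for planted-subgroup recovery
#'
#' A synthetic-survey configuration built for validating the spatial stage
#' end to end: a cohort of 3000 respondents whose doses are nearly constant
#' (independent of all factors), plus one planted subgroup (12%) that is
#' compact in factor space, offset from the bulk on every factor except its
#' dose-driving one, whose two perception modes (gap 0.5 latent units) split
#' the subgroup's doses to the extremes (0 vs 5). Under these conditions the
#' aggregated spatial signal should peak on the planted subgroup, the top
#' ROI should recover its membership, the correlation screen should flag
#' the driving factor, and globally permuting doses should collapse the
#' signal maximum. Recommended analysis settings for this benchmark: the
#' deterministic PCA embedding and a cell occupancy floor of 75 (high
#' enough that the plug-in estimator's small-sample bias stays well below
#' the planted signal).
#'
#' @param seed Generator seed.
#' @param n_respondents Cohort size (default 3000).
#' @return A `synthetic_config`.
#' @export
roi_benchmark_config <- function(seed = 1L, n_respondents = 3000L) {
  specs <- default_scale_specs()
  fids <- unlist(lapply(specs, function(s) paste0(s$prefix, "-c",
                                                  seq_len(s$n_clusters))))
  center <- stats::setNames(rep(1.3, length(fids)), fids)
  center["C-c1"] <- 0
  synthetic_config(
    n_respondents = n_respondents, scales = specs,
    dose_model = list(intercept = 1.0, coefficients = c(), noise_sd = 0.15),
    planted_subgroups = list(list(
      fraction = 0.12, center = center, spread = 0.15, radial_sd = 0,
      driver = "C-c1", driver_gap = 0.5, strength = 1)),
    seed = seed)
}

# internal: factor ids and the deterministic item partition of a config
config_layout <- function(config) {
  factor_ids <- character(); item_partition <- integer(); item_scale <- character()
  global_cluster <- 0L
  for (s in config$scales) {
    sizes <- rep(s$n_items %/% s$n_clusters, s$n_clusters)
    extra <- s$n_items %% s$n_clusters
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    items <- paste0(s$prefix, "i", seq_len(s$n_items))
    part <- rep(global_cluster + seq_len(s$n_clusters), times = sizes)
    names(part) <- items
    item_partition <- c(item_partition, part)
    item_scale <- c(item_scale, rep(s$scale_id, s$n_items))
    factor_ids <- c(factor_ids, paste0(s$prefix, "-c", seq_len(s$n_clusters)))
    global_cluster <- global_cluster + s$n_clusters
  }
  list(factor_ids = factor_ids, item_partition = item_partition,
       item_scale = item_scale)
}

# internal: structural randomness shared by generate_dataset() and
# ground_truth(): subgroup memberships (reverse items are deterministic —
# the first round(fraction * n_items) items of each scale).
plan_structure <- function(config) {
  layout <- config_layout(config)
  n <- config$n_respondents
  ids <- sprintf("r%04d", seq_len(n))
  withr::with_seed(derive_seed(config$seed, 1L), {
    available <- seq_len(n)
    subgroups <- lapply(config$planted_subgroups, function(g) {
      size <- round(g$fraction * n)
      members <- sort(sample(available, size))
      available <<- setdiff(available, members)
      list(member_ids = ids[members], members = members,
           driver = g$driver, center = g$center,
           spread = if (is.null(g$spread)) 0.25 else g$spread,
           radial_sd = if (is.null(g$radial_sd)) 0 else g$radial_sd,
           driver_gap = if (is.null(g$driver_gap)) 0 else g$driver_gap,
           strength = if (is.null(g$strength)) 1 else g$strength,
           demographics = g$demographics)
    })
    c(layout, list(respondent_ids = ids, subgroups = subgroups))
  })
}

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + 7919 * stream) %% 2147483629)
}

#' Planted ground truth of a synthetic configuration
#'
#' Returns the structure the generator plants — the item-to-cluster
#' partition, the factor identifiers, and the subgroup memberships with
#' their dose-driving factors — without generating responses, so tests can
#' assert recovery against it.
#'
#' @param config A `synthetic_config`.
#' @return List with `factor_ids`, `item_partition` (named integer vector
#'   over all items), `item_scale`, `respondent_ids`, and `subgroups` (each
#'   with `member_ids`, `driver`, `strength`).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  plan <- plan_structure(config)
  plan[c("factor_ids", "item_partition", "item_scale", "respondent_ids",
         "subgroups")]
}

#' Generate a synthetic survey with known ground truth
#'
#' Items follow a single-factor model per planted cluster: each item is
#' `loading * cluster latent + independent noise`, discretized at
#' equiprobable normal cutpoints into the scale's Likert range. Loadings are
#' calibrated by inverting the exact discretization map ([likert_corr()]) so
#' that realized post-discretization within- and between-cluster
#' correlations approach the configured targets at large n. A configurable fraction of each scale's
#' items is stored reverse-phrased (reflected), so that [reverse_score()]
#' restores alignment. The dose is a clipped, rounded linear combination of
#' the latent factors plus Gaussian noise; inside each planted subgroup the
#' subgroup's dose rule overrides it (members above the subgroup median of
#' the driving factor get dose 5, the rest dose 0, with probability
#' `strength`). Demographics are drawn from the cohort distributions, with
#' per-subgroup overrides. Everything is determined by `config$seed`.
#'
#' @param config A `synthetic_config`.
#' @return List with `dataset` (a `survey_dataset`) and `truth` (the
#'   [ground_truth()] structure plus the latent factor matrix).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  plan <- plan_structure(config)
  n <- config$n_respondents
  nf <- length(plan$factor_ids)

  withr::with_seed(derive_seed(config$seed, 2L), {
    # latent factors, scale by scale (between-cluster correlation within a
    # scale comes from a shared scale-level component)
    latents <- matrix(0, n, nf, dimnames = list(plan$respondent_ids, plan$factor_ids))
    col <- 0L
    for (s in config$scales) {
      L0 <- s$likert[2L] - s$likert[1L] + 1L
      g <- calibrate_latent_corr(s$between_pcc, L0) /
        calibrate_latent_corr(s$within_pcc, L0)
      shared <- stats::rnorm(n)
      for (cl in seq_len(s$n_clusters)) {
        col <- col + 1L
        latents[, col] <- sqrt(g) * shared + sqrt(1 - g) * stats::rnorm(n)
      }
    }
    # compact planted subgroups in factor space; the driver factor is
    # bimodal within the subgroup (two perception modes, gap 2 * driver_gap)
    for (sg in plan$subgroups) {
      m <- length(sg$members)
      ctr <- sg$center
      if (is.null(names(ctr))) ctr <- stats::setNames(rep_len(ctr, nf), plan$factor_ids)
      # radial scatter: members share the profile direction but differ in
      # its overall intensity, so the subgroup spreads along its own offset
      # axis in the embedding rather than along any single factor
      intensity <- 1 + sg$radial_sd * stats::rnorm(m)
      for (f in names(ctr))
        latents[sg$members, f] <- ctr[[f]] * intensity +
          stats::rnorm(m, sd = sg$spread)
      if (sg$driver_gap > 0) {
        ctr_d <- if (sg$driver %in% names(ctr)) ctr[[sg$driver]] else 0
        signs <- sample(rep(c(-1, 1), length.out = m))
        latents[sg$members, sg$driver] <- ctr_d + sg$driver_gap * signs +
          stats::rnorm(m, sd = sg$spread)
      }
    }

    # items: loading * latent + noise, discretized at equiprobable cutpoints
    responses <- matrix(0L, n, length(plan$item_partition),
                        dimnames = list(plan$respondent_ids,
                                        names(plan$item_partition)))
    scales_out <- list()
    for (s in config$scales) {
      L <- s$likert[2L] - s$likert[1L] + 1L
      lam <- sqrt(calibrate_latent_corr(s$within_pcc, L))
      cuts <- stats::qnorm(seq_len(L - 1L) / L)
      item_ids <- names(plan$item_partition)[plan$item_scale == s$scale_id]
      for (j in seq_along(item_ids)) {
        f <- plan$item_partition[[item_ids[j]]]
        z <- lam * latents[, f] + sqrt(1 - lam^2) * stats::rnorm(n)
        responses[, item_ids[j]] <-
          s$likert[1L] + findInterval(z, cuts)
      }
      n_rev <- round(s$reverse_fraction * s$n_items)
      rev_items <- item_ids[seq_len(n_rev)]
      responses[, rev_items] <-
        s$likert[1L] + s$likert[2L] - responses[, rev_items, drop = FALSE]
      scales_out[[s$scale_id]] <- scale_definition(
        s$scale_id, item_ids, s$likert[1L], s$likert[2L],
        reverse_items = rev_items, prefix = s$prefix)
    }

    # dose: linear in the latents, noise, clipped to 0..5
    beta <- stats::setNames(rep(0, nf), plan$factor_ids)
    cf <- config$dose_model$coefficients
    beta[names(cf)] <- cf
    raw <- config$dose_model$intercept + as.numeric(latents %*% beta) +
      stats::rnorm(n, sd = config$dose_model$noise_sd)
    dose <- pmin(5L, pmax(0L, as.integer(round(raw))))
    for (sg in plan$subgroups) {
      m <- sg$members
      drv <- latents[m, sg$driver]
      override <- ifelse(drv > stats::median(drv), 5L, 0L)
      use <- stats::runif(length(m)) < sg$strength
      dose[m][use] <- override[use]
    }

    # demographics with subgroup overrides
    demo <- data.frame(row.names = plan$respondent_ids)
    for (v in names(config$demographics)) {
      p <- config$demographics[[v]]
      demo[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
      for (sg in plan$subgroups) {
        ov <- sg$demographics[[v]]
        if (!is.null(ov))
          demo[sg$members, v] <- sample(names(ov), length(sg$members),
                                        replace = TRUE, prob = ov)
      }
    }

    dataset <- survey_dataset(responses, dose, demo, scales_out)
    truth <- c(plan[c("factor_ids", "item_partition", "item_scale",
                      "respondent_ids", "subgroups")],
               list(latents = latents))
    list(dataset = dataset, truth = truth)
  })
}
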