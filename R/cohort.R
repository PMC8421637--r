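#' Generate a synthetic two-group, two-scan cohort
#'
#' Builds a cohort mirroring a pre/post exposure study design: two groups
#' (`dependent`, `control`), two scans per subject, demographic covariates
#' and clinical scores drawn from configurable group distributions, and
#' planted switching structure. Each subject's scans share a base design;
#' per-subject switch events are drawn at random (count `Poisson(events_lambda)`
#' for the pre scan) and the post scan additionally receives
#' `Poisson(effect^2)` extra events, so the standardized paired post-minus-pre
#' increment in global planted rate is approximately `effect` (each extra
#' event contributes one module switch, and the shared pre events cancel in
#' the paired difference, leaving `mean/sd = effect^2/sqrt(effect^2) = effect`).
#'
#' Outcome values in `$outcomes` are noisy estimates of the *planted*
#' per-node switching rates: the rate computed from each scan's schedule via
#' [planted_switch_rate()] plus independent Gaussian measurement noise of
#' standard deviation `rate_noise_sd` (emulating the estimation noise of a
#' finite-repetition pipeline; estimates may dip slightly below 0), with
#' subnetwork/global aggregates taken over the noisy node values. They
#' exercise the statistics stage without running community detection; the
#' extra-event mean is calibrated against both the Poisson event variance and
#' this noise so the standardized paired effect is `effect`. Full signal
#' matrices are regenerated on demand with [subject_scan()]. Deterministic
#' given `seed`; per-subject and per-scan random streams are derived with
#' fixed offsets, so adding subjects never perturbs earlier ones.
#'
#' @param n_per_group Named integer vector `c(dependent = , control = )`,
#'   default the study arm sizes 24 and 26.
#' @param design_by_condition List with elements `pre` and `post`, each a
#'   [planted_design()] used as the base for that condition (default: one
#'   shared default design).
#' @param effect Standardized (paired Cohen's d) post-minus-pre increment in
#'   global planted rate; 0 for a null cohort.
#' @param seed Master integer seed.
#' @param window A [window_config()]; must be valid for the designs.
#' @param atlas Node-to-subnetwork map (data frame `node_id`, `subnetwork`);
#'   default [synthetic_atlas()] of the right size.
#' @param events_lambda Mean number of per-subject switch events in the pre
#'   scan (default 20).
#' @param rate_noise_sd Standard deviation of the per-node measurement noise
#'   added to the outcome rates (default 0.01).
#' @param score_rate_corr Named vector of target Spearman correlations
#'   between each score and the subject's pre-scan global planted rate,
#'   applied within groups where the score exists. Default couples BQDS at
#'   0.47 in the dependent group.
#' @param include_scans If `TRUE`, attach generated [timeseries_scan()]
#'   objects under `$scans` (memory heavy for large designs).
#' @return An object of class `netswitch_cohort`: list with `subjects`
#'   (one row per subject: group, covariates, scores, mean FD), `outcomes`
#'   (long table: subject_id, scan, level, outcome, value), `designs`,
#'   `atlas`, `window`, `seed`.
#' @examples
#' coh <- generate_cohort(
#'   n_per_group = c(dependent = 4, control = 4),
#'   design_by_condition = list(
#'     pre = planted_design(n_nodes = 12, n_volumes = 120,
#'                          base_partition = rep(1:3, each = 4))),
#'   effect = 0, seed = 7,
#'   window = window_config(width = 30, step = 5, trim_initial = 10))
#' head(coh$subjects)
#' @export
generate_cohort <- function(n_per_group = c(dependent = 24L, control = 26L),
                            design_by_condition = NULL,
                            effect = 0, seed = 1L,
                            window = window_config(),
                            atlas = NULL,
                            events_lambda = 20,
                            rate_noise_sd = 0.01,
                            score_rate_corr = c(BQDS = 0.47),
                            include_scans = FALSE) {
  if (is.null(names(n_per_group))) names(n_per_group) <- c("dependent", "control")
  if (!all(c("dependent", "control") %in% names(n_per_group))) {
    stop("n_per_group needs entries 'dependent' and 'control'", call. = FALSE)
  }
  if (any(n_per_group < 2)) stop("need at least 2 subjects per group", call. = FALSE)
  if (effect < 0) stop("effect must be >= 0", call. = FALSE)
  if (is.null(design_by_condition)) design_by_condition <- list(pre = planted_design())
  if (is.null(design_by_condition$post)) design_by_condition$post <- design_by_condition$pre
  base_pre <- design_by_condition$pre
  base_post <- design_by_condition$post
  stopifnot(inherits(base_pre, "planted_design"),
            inherits(base_post, "planted_design"))
  if (base_pre$n_nodes != base_post$n_nodes) {
    stop("pre and post designs must share n_nodes", call. = FALSE)
  }
  n_nodes <- base_pre$n_nodes
  if (is.null(atlas)) atlas <- synthetic_atlas(n_nodes)

  W <- nrow(sliding_windows(base_pre$n_volumes, window))
  ids <- c(sprintf("dep%02d", seq_len(n_per_group[["dependent"]])),
           sprintf("ctl%02d", seq_len(n_per_group[["control"]])))
  groups <- rep(c("dependent", "control"), n_per_group[c("dependent", "control")])
  n_total <- length(ids)

  # theoretical moments of the pre global outcome (planted rate + noise),
  # used to standardize the rate when coupling scores to it (keeps earlier
  # subjects' draws untouched when the cohort grows)
  base_rate <- mean(planted_switch_rate(base_pre, window))
  cap <- n_nodes * (W - 1)  # one extra event ~ one switch ~ 1/cap in rate
  mu_rate <- base_rate + events_lambda / cap
  sd_rate <- sqrt(events_lambda / cap^2 + rate_noise_sd^2 / n_nodes)

  designs <- vector("list", n_total)
  names(designs) <- ids
  subj_rows <- vector("list", n_total)
  outcome_rows <- vector("list", n_total)
  pre_global <- numeric(n_total)
  latent <- matrix(NA_real_, n_total, 10,
                   dimnames = list(ids, c("age", "edu", "BQDS", "BDI", "BAI",
                                          "dur", "eBQDS", "eBDI", "eBAI", "edur")))

  # Mean extra-event count delta: the paired global difference is
  # X/cap + eps with X ~ Poisson(delta) and eps the paired measurement
  # noise (sd s_n); solve mean/sd = effect for delta.
  s_n2 <- 2 * rate_noise_sd^2 / n_nodes
  u <- (effect^2 / cap + sqrt(effect^4 / cap^2 + 4 * effect^2 * s_n2)) / 2
  delta <- u * cap
  for (j in seq_len(n_total)) {
    grp <- groups[j]
    s_pre <- derive_seed(seed, 2000L + j)
    s_post <- derive_seed(seed, 3000L + j)
    ev_pre <- with_seed(s_pre, draw_events(base_pre, window,
                                           stats::rpois(1L, events_lambda)))
    d_pre <- set_design_events(base_pre, ev_pre)
    d_post_base <- set_design_events(base_post, ev_pre)
    ev_extra <- with_seed(s_post, draw_events(d_post_base, window,
                                              stats::rpois(1L, delta)))
    d_post <- set_design_events(base_post, rbind(ev_pre, ev_extra))
    designs[[j]] <- list(pre = d_pre, post = d_post,
                         seed_pre = s_pre, seed_post = s_post)

    noise <- with_seed(derive_seed(seed, 5000L + j),
                       stats::rnorm(2L * n_nodes, sd = rate_noise_sd))
    r_pre <- planted_switch_rate(d_pre, window) + noise[seq_len(n_nodes)]
    r_post <- planted_switch_rate(d_post, window) + noise[n_nodes + seq_len(n_nodes)]
    pre_global[j] <- mean(r_pre)

    latent[j, ] <- with_seed(derive_seed(seed, 1000L + j), stats::rnorm(10))
    fd <- mean_fd(scan_motion(base_pre$n_volumes, s_pre))

    subj_rows[[j]] <- data.frame(subject_id = ids[j], group = grp,
                                 mean_fd = fd, stringsAsFactors = FALSE)
    outcome_rows[[j]] <- rbind(outcomes_for(ids[j], "pre", r_pre, atlas),
                               outcomes_for(ids[j], "post", r_post, atlas))
  }

  subjects <- do.call(rbind, subj_rows)
  subjects$age <- ifelse(groups == "dependent", 23.54 + 3.87 * latent[, "age"],
                         24.50 + 1.48 * latent[, "age"])
  subjects$education <- ifelse(groups == "dependent",
                               15.13 + 1.73 * latent[, "edu"], 16.00)
  z_rate <- (pre_global - mu_rate) / sd_rate
  score_def <- list(
    BQDS = list(dep = c(7.42, 1.86), ctl = NULL),
    BDI = list(dep = c(10.58, 6.68), ctl = c(4.04, 4.65)),
    BAI = list(dep = c(28.50, 6.20), ctl = c(23.27, 2.68)),
    duration = list(dep = c(7.75, 4.28), ctl = NULL))
  lat_col <- c(BQDS = "BQDS", BDI = "BDI", BAI = "BAI", duration = "dur")
  err_col <- c(BQDS = "eBQDS", BDI = "eBDI", BAI = "eBAI", duration = "edur")
  for (sc in names(score_def)) {
    rho <- unname(score_rate_corr[sc])
    rho <- if (is.na(rho) || !length(rho)) 0 else rho
    rp <- 2 * sin(pi * min(abs(rho), 0.999) / 6) * sign(rho)
    z <- rp * z_rate + sqrt(1 - rp^2) * latent[, err_col[sc]]
    z0 <- latent[, lat_col[sc]]
    vals <- rep(NA_real_, n_total)
    for (grp in c("dependent", "control")) {
      pars <- score_def[[sc]][[if (grp == "dependent") "dep" else "ctl"]]
      if (is.null(pars)) next
      sel <- groups == grp
      zz <- if (rho != 0 && grp == "dependent") z[sel] else z0[sel]
      vals[sel] <- pmax(0, pars[1L] + pars[2L] * zz)
    }
    subjects[[sc]] <- vals
  }
  rownames(subjects) <- NULL

  out <- structure(list(subjects = subjects,
                        outcomes = do.call(rbind, outcome_rows),
                        designs = designs, atlas = atlas, window = window,
                        effect = effect, seed = as.integer(seed)),
                   class = "netswitch_cohort")
  if (include_scans) {
    out$scans <- lapply(ids, function(id) {
      list(pre = subject_scan(out, id, "pre"),
           post = subject_scan(out, id, "post"))
    })
    names(out$scans) <- ids
  }
  out
}

# Random switch events: nodes uniform, volumes away from the series edges so
# every event's majority flip registers in some window, target module drawn
# different from the node's scheduled label at that volume (given the
# design's existing events), so each event is a real switch.
draw_events <- function(design, window, k) {
  if (k == 0L) return(NULL)
  T_ <- design$n_volumes
  lo <- window$trim_initial + window$width + 1L
  hi <- T_ - window$width
  if (hi < lo) stop("design too short for switch events under this window",
                    call. = FALSE)
  lab <- schedule_matrix(design)
  mods <- sort(unique(as.vector(lab)))
  node <- sample.int(design$n_nodes, k, replace = TRUE)
  volume <- if (hi == lo) rep(lo, k) else sample(seq.int(lo, hi), k, replace = TRUE)
  module <- vapply(seq_len(k), function(e) {
    cur <- lab[node[e], volume[e]]
    pool <- setdiff(mods, cur)
    if (!length(pool)) cur else pool[sample.int(length(pool), 1L)]
  }, integer(1L))
  data.frame(node = node, volume = volume, module = module)
}

set_design_events <- function(design, events) {
  base <- design$partition_schedule[[1L]]$labels
  planted_design(n_nodes = design$n_nodes, n_volumes = design$n_volumes,
                 sampling_interval = design$sampling_interval,
                 base_partition = base,
                 within_module_corr = design$within_module_corr,
                 noise_sd = design$noise_sd, band = design$band,
                 switch_events = events)
}

outcomes_for <- function(id, scan, node_rates, atlas) {
  subnet <- atlas$subnetwork[match(names(node_rates), atlas$node_id)]
  sub_means <- tapply(node_rates, subnet, mean)
  data.frame(
    subject_id = id, scan = scan,
    level = c("global", rep("subnetwork", length(sub_means)),
              rep("node", length(node_rates))),
    outcome = c("global", names(sub_means), names(node_rates)),
    value = c(mean(node_rates), as.numeric(sub_means), unname(node_rates)),
    stringsAsFactors = FALSE)
}

#' Regenerate one subject's scan
#'
#' Materializes the signal matrix and motion trace of a cohort subject's pre
#' or post scan from its stored design and derived seed; bit-identical across
#' calls.
#'
#' @param cohort A [generate_cohort()] result.
#' @param subject_id Subject identifier.
#' @param scan `"pre"` or `"post"`.
#' @return A [timeseries_scan()].
#' @export
subject_scan <- function(cohort, subject_id, scan = c("pre", "post")) {
  scan <- match.arg(scan)
  stopifnot(inherits(cohort, "netswitch_cohort"))
  d <- cohort$designs[[subject_id]]
  if (is.null(d)) stop(sprintf("unknown subject '%s'", subject_id), call. = FALSE)
  generate_scan(d[[scan]],
                seed = if (scan == "pre") d$seed_pre else d$seed_post)
}

#' @export
print.netswitch_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf(
    "<netswitch_cohort> %d subjects (%s), 2 scans each, %d-node designs, effect = %g\n",
    nrow(x$subjects),
    paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
    x$designs[[1L]]$pre$n_nodes, x$effect))
  invisible(x)
}
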