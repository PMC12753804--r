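# End-to-end orchestration: synthetic ensemble (or user data) -> distance
# features -> TICA -> k-means microstates -> reversible MSM -> implied
# timescales -> PCCA+ macrostates -> kinetics, geometry and contacts.

#' Pipeline configuration
#'
#' The `full` profile carries the parameters of a full-scale MD study
#' (1500 microstates, lag 1500 ps, 10 macrostates); the `fixture` profile
#' is the reduced desk-scale setting used with the synthetic systems
#' (k = 200, lag 1 frame, 60 x 5000 frames).
#'
#' @param system "xpd" or "ding"
#' @param profile "fixture" or "full"
#' @param ... overrides of individual fields
#' @return config list
#' @export
pipeline_config <- function(system = c("xpd", "ding"),
                            profile = c("fixture", "full"), ...) {
  system <- match.arg(system)
  profile <- match.arg(profile)
  base <- list(
    system = system,
    n_traj = 60L, n_frames = 5000L, sigma = 0.2, save_stride = 1L,
    feature_stride = 6L, include_dna = TRUE,
    tica_lag = 5L, n_ics = 10L,
    k_micro = 200L, msm_lag = 1L,
    max_macro = 12L, n_macro = NA_integer_,   # NA: select from timescales
    seed = 1L)
  if (profile == "full") {
    base$k_micro <- 1500L
    base$msm_lag <- 1500L     # frames of 1 ps: lag 1500 ps
    base$n_macro <- 10L
  }
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(base)))
  config <- modifyList(base, ov)
  if (config$k_micro > config$n_traj * config$n_frames)
    stop("config invalid: more microstates than frames")
  if (config$tica_lag + 2 > config$n_frames || config$msm_lag >= config$n_frames)
    stop("config invalid: lag exceeds trajectory length")
  config
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with fields of [pipeline_config()]
#' @return config list
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(system = y$system %||% "xpd",
                 profile = y$profile %||% "fixture"),
            y[setdiff(names(y), c("system", "profile"))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a synthetic fixture
#'
#' Generates the seeded ensemble (trajectory starts cycle round-robin
#' through the fixture states, emulating runs launched from replicas along
#' the transition path), computes distance features and per-frame
#' constriction widths in one streaming pass, fits TICA, clusters the
#' projections into microstates, estimates the reversible MSM, selects the
#' macrostate count from the implied-timescale spectrum (unless fixed in
#' the config), coarse-grains with PCCA+, and maps macrostates onto the
#' fixture's state templates by projecting the noise-free templates.
#'
#' @param config from [pipeline_config()]
#' @param fixture_data optional prebuilt `list(topology, fixture)`
#' @return list with the fitted models and summary tables (see fields)
#' @export
run_pipeline <- function(config, fixture_data = NULL) {
  t0 <- Sys.time()
  if (is.null(fixture_data)) {
    fixture_data <- if (config$system == "xpd") build_xpd_fixture()
                    else build_ding_fixture()
  }
  topology <- fixture_data$topology
  fixture <- fixture_data$fixture
  spec <- build_feature_spec(topology, stride = config$feature_stride,
                             include_dna = config$include_dna)
  cons <- fixture_constriction_defs(fixture)

  feats <- vector("list", config$n_traj)
  labels_true <- vector("list", config$n_traj)
  w1 <- vector("list", config$n_traj)
  w2 <- vector("list", config$n_traj)
  emit_ensemble(fixture, config$n_traj, config$n_frames, seed = config$seed,
                sigma = config$sigma, save_stride = config$save_stride,
                callback = function(i, traj, lab) {
    feats[[i]] <<- compute_features(traj, spec)
    labels_true[[i]] <<- lab
    ws <- wall_width_series(traj, cons, topology)
    w1[[i]] <<- ws$c1; w2[[i]] <<- ws$c2
  })
  dt_frame <- fixture$dt_s * config$save_stride

  tica <- fit_tica(feats, lag = config$tica_lag, n_components = config$n_ics)
  Y <- matrix(0, config$n_traj * config$n_frames, tica$n_components)
  for (i in seq_len(config$n_traj)) {
    Y[((i - 1) * config$n_frames + 1):(i * config$n_frames), ] <-
      tica_project(tica, feats[[i]])
    feats[i] <- list(NULL)        # release: the feature stack is the peak
  }
  feats <- NULL

  micro <- kmeans_cluster(Y, k = config$k_micro, seed = config$seed)
  lab_list <- split_labels(micro$labels, config$n_traj, config$n_frames)
  C <- count_matrix(lab_list, tau = config$msm_lag, k = config$k_micro)
  msm <- estimate_reversible_T(C)
  its <- implied_timescales(msm, tau = config$msm_lag, dt_s = dt_frame)
  n_macro <- if (is.na(config$n_macro))
    select_n_macrostates(its, max_m = config$max_macro,
                         floor_s = config$msm_lag * dt_frame)
  else config$n_macro
  macro <- pcca_coarse_grain(msm, n_macro)

  # per-frame macrostate labels (NA for frames in trimmed microstates)
  micro_to_macro <- rep(NA_integer_, config$k_micro)
  micro_to_macro[msm$active] <- macro$crisp
  frame_macro <- micro_to_macro[micro$labels]

  template_map <- map_templates_to_macrostates(fixture, spec, tica, micro,
                                               micro_to_macro)
  kin <- mfpt_and_rates(msm, macro, tau = config$msm_lag, dt_s = dt_frame)

  pathway <- NULL
  src <- template_map[fixture$on_path[1]]
  snk <- template_map[fixture$on_path[length(fixture$on_path)]]
  if (!is.na(src) && !is.na(snk) && src != snk)
    pathway <- tryCatch(decompose_pathway(macro, src, snk),
                        error = function(e) NULL)

  list(config = config, topology = topology, fixture = fixture,
       feature_spec = spec, tica = tica, projections = Y,
       micro = micro, msm = msm, its = its, n_macro = n_macro,
       macro = macro, frame_macro = frame_macro,
       labels_true = unlist(labels_true),
       widths = list(c1 = unlist(w1), c2 = unlist(w2)),
       template_map = template_map, kinetics = kin, pathway = pathway,
       dt_frame = dt_frame,
       runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

split_labels <- function(labels, n_traj, n_frames) {
  lapply(seq_len(n_traj), function(i)
    labels[((i - 1) * n_frames + 1):(i * n_frames)])
}

fixture_constriction_defs <- function(fixture) {
  list(c1 = list(wall_a = fixture$constrictions$c1$wall_a,
                 wall_b = fixture$constrictions$c1$wall_b),
       c2 = list(wall_a = fixture$constrictions$c2$wall_a,
                 wall_b = fixture$constrictions$c2$wall_b))
}

# per-frame widths of both constrictions, vectorized over frames
wall_width_series <- function(traj, cons, topology) {
  co <- traj$coordinates
  nf <- dim(co)[1]
  lapply(cons, function(cd) {
    ga <- resolve_residue_atoms(topology, cd$wall_a)
    gb <- resolve_residue_atoms(topology, cd$wall_b)
    ia <- unlist(ga); ib <- unlist(gb)
    # distance stack: frames x (atoms_a * atoms_b)
    d2 <- array(0, c(nf, length(ia), length(ib)))
    for (p in seq_along(ia)) {
      for (q in seq_along(ib)) {
        d2[, p, q] <- (co[, ia[p], 1] - co[, ib[q], 1])^2 +
                      (co[, ia[p], 2] - co[, ib[q], 2])^2 +
                      (co[, ia[p], 3] - co[, ib[q], 3])^2
      }
    }
    ra <- rep(seq_along(ga), vapply(ga, length, 0L))
    rb <- rep(seq_along(gb), vapply(gb, length, 0L))
    # directed mean of per-residue minima, both directions
    row_mins <- function(sl) {
      m <- matrix(sl, nrow = nf)
      do.call(pmin, lapply(seq_len(ncol(m)), function(cc) m[, cc]))
    }
    mins_a <- vapply(seq_along(ga), function(r)
      row_mins(d2[, ra == r, , drop = FALSE]), numeric(nf))
    mins_b <- vapply(seq_along(gb), function(r)
      row_mins(d2[, , rb == r, drop = FALSE]), numeric(nf))
    (rowMeans(sqrt(mins_a)) + rowMeans(sqrt(mins_b))) / 2
  })
}

#' Map fixture state templates to pipeline macrostates
#'
#' Projects each noise-free state template through the fitted TICA model,
#' assigns it to its nearest microstate center and reads off that
#' microstate's macrostate. Returns a named integer vector (NA when the
#' template's microstate was trimmed).
#'
#' @param fixture `helimsm_fixture`
#' @param spec feature spec used by the pipeline
#' @param tica fitted TICA model
#' @param micro fitted microstate model
#' @param micro_to_macro integer map (length k)
#' @return named integer vector, one entry per fixture state
#' @export
map_templates_to_macrostates <- function(fixture, spec, tica, micro,
                                         micro_to_macro) {
  Xt <- t(vapply(fixture$templates, function(tmpl) {
    d <- tmpl[spec$pairs[, 1], , drop = FALSE] -
         tmpl[spec$pairs[, 2], , drop = FALSE]
    sqrt(rowSums(d^2))
  }, numeric(nrow(spec$pairs))))
  Yt <- tica_project(tica, Xt)
  mt <- assign_microstates(micro, Yt)
  setNames(micro_to_macro[mt], fixture$state_ids)
}

#' Widths of the two constrictions per macrostate
#'
#' @param result output of [run_pipeline()]
#' @return data.frame: `macrostate`, `template` (mapped fixture state or
#'   NA), `c1_mean`, `c1_sd`, `c2_mean`, `c2_sd`, `n_frames`
#' @export
macrostate_width_table <- function(result) {
  fm <- result$frame_macro
  ok <- !is.na(fm)
  agg <- function(w) {
    mean_ <- tapply(w[ok], fm[ok], mean)
    sd_ <- tapply(w[ok], fm[ok], sd)
    list(mean = mean_, sd = sd_)
  }
  a1 <- agg(result$widths$c1); a2 <- agg(result$widths$c2)
  ms <- as.integer(names(a1$mean))
  inv <- vapply(ms, function(m) {
    hits <- names(result$template_map)[which(result$template_map == m)]
    if (length(hits) == 1) hits else NA_character_
  }, "")
  data.frame(macrostate = ms, template = inv,
             c1_mean = as.vector(a1$mean), c1_sd = as.vector(a1$sd),
             c2_mean = as.vector(a2$mean), c2_sd = as.vector(a2$sd),
             n_frames = as.vector(table(fm[ok])))
}

#' Kinetic estimate from a long state-label sequence
#'
#' Estimates the reversible transition matrix of the fixture's state-level
#' chain from a simulated label sequence (count at lag 1, reversible MLE)
#' and solves the first-passage system on the estimate. This is the
#' estimator used for kinetic parameter recovery.
#'
#' @param fixture `helimsm_fixture`
#' @param n_frames sequence length (default 1e7)
#' @param seed RNG seed
#' @return list with `T` (estimated), `mfpt_s` (function(from, to)),
#'   `active` state ids
#' @export
estimate_fixture_kinetics <- function(fixture, n_frames = 1e7, seed = 1L) {
  lab <- simulate_state_sequence(fixture, n_frames, seed = seed)
  idx <- match(lab, fixture$state_ids)
  C <- count_matrix(idx, tau = 1L, k = length(fixture$state_ids))
  msm <- estimate_reversible_T(C)
  ids <- fixture$state_ids[msm$active]
  mfpt_fun <- function(from, to) {
    i <- match(from, ids); j <- match(to, ids)
    if (is.na(i) || is.na(j)) stop("state not in active set")
    chain_mfpt(msm$T, j)[i] * fixture$dt_s
  }
  list(T = msm$T, pi = msm$pi, active_ids = ids, mfpt_s = mfpt_fun)
}
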