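#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generators are deterministic without clobbering the
#' session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Configuration of the synthetic accession-panel generator
#'
#' Ranges and noise levels from which accession-level ground truths are
#' drawn. Defaults are anchored to the trait ranges a sorghum diversity
#' panel exhibits: apparent quantum yields of 0.04-0.07, A-gs coupling
#' slopes of 150-220 umol CO2 mol^-1 H2O, stomatal time constants spanning
#' 42-1062 s (assimilation: 92-1235 s) with positive cross-trait
#' correlation, and surface-asymmetric stomatal densities (abaxial 51-185,
#' adaxial 28-121 mm^-2).
#'
#' The panel-level A-gs structure is generated by construction: each
#' accession's saturating conductance is derived from its saturating
#' assimilation through a common anchor relation (slope `anchor_slope`,
#' intercept `anchor_intercept`) with `gssat_cv` multiplicative scatter, and
#' the accession's own coupling line (slope drawn from `coupling_slope`)
#' then passes through that point. This embodies the tight panel-wide
#' Asat-gssat coupling the analysis assumes while keeping per-accession
#' coupling intercepts negative, so intrinsic water use efficiency rises
#' with light.
#'
#' @param phi,Amax,Rd,coupling_slope,lam,SD_ab,SD_ad,gcl Uniform draw
#'   ranges `c(lo, hi)` for the accession truths (units: mol mol^-1;
#'   umol m^-2 s^-1; umol m^-2 s^-1; umol CO2 mol^-1 H2O; s; mm^-2; mm^-2;
#'   um).
#' @param pore_frac Pore length as a fraction of guard cell length.
#' @param k_gs,k_A Log-uniform draw ranges for the gs and A time
#'   constants, s.
#' @param tau_rho Target Pearson correlation between `k_A` and `k_gs`
#'   across accessions (Gaussian copula).
#' @param anchor_slope,anchor_intercept Panel anchor relation Asat =
#'   intercept + slope * gssat (midpoints of the per-accession coupling
#'   ranges).
#' @param gssat_cv Multiplicative scatter (CV) of gssat about the anchor.
#' @param noise_A,noise_gs Gaussian measurement noise SDs for A
#'   (umol m^-2 s^-1) and gs (mol m^-2 s^-1).
#' @param ci_ca_target Target Ci/Ca ratio at saturating light.
#' @param field_area_mm2 Microscope field-of-view area at the x10
#'   objective, mm^2 (assumed value; the instrument does not report it).
#' @return A list of class `"panel_config"`.
#' @export
panel_config <- function(phi = c(0.04, 0.07), Amax = c(18, 45),
                         Rd = c(0.5, 2.5), coupling_slope = c(150, 220),
                         lam = c(20, 120),
                         k_gs = c(42, 1062), k_A = c(92, 1235),
                         tau_rho = 0.6,
                         anchor_slope = 185, anchor_intercept = -9,
                         gssat_cv = 0.05,
                         SD_ab = c(51, 185), SD_ad = c(28, 121),
                         gcl = c(30, 45), pore_frac = c(0.45, 0.65),
                         noise_A = 0.3, noise_gs = 0.005,
                         ci_ca_target = 0.30, field_area_mm2 = 0.29) {
  cfg <- as.list(environment())
  structure(cfg, class = "panel_config")
}

#' A single accession ground truth
#'
#' Convenience constructor of one accession's true parameter set, with
#' mid-range defaults. Useful for examples and focused simulations; panels
#' are drawn with [sample_panel()].
#'
#' @param accession,plant_id Identifiers.
#' @param phi,Amax,Rd Light-response truth (quantum yield, asymptotic
#'   gross assimilation, dark respiration).
#' @param coupling_slope,coupling_intercept A = intercept + slope * gs
#'   coupling line (umol CO2 mol^-1 H2O; umol m^-2 s^-1).
#' @param k_gs,k_A,lam Induction time constants and shared lag, s.
#' @param SD_ab,SD_ad Stomatal densities, mm^-2.
#' @param gcl,pore Guard cell and pore lengths, um.
#' @param noise_A,noise_gs Measurement noise SDs.
#' @return A one-row data frame of class `"accession_truth"`.
#' @export
accession_truth <- function(accession = "ACC001", plant_id = "ACC001_p1",
                            phi = 0.05, Amax = 35, Rd = 1.5,
                            coupling_slope = 185, coupling_intercept = -9,
                            k_gs = 300, k_A = 250, lam = 60,
                            SD_ab = 118, SD_ad = 75, gcl = 38, pore = 20,
                            noise_A = 0.3, noise_gs = 0.005) {
  out <- data.frame(accession = accession, plant_id = plant_id,
                    phi = phi, Amax = Amax, Rd = Rd,
                    coupling_slope = coupling_slope,
                    coupling_intercept = coupling_intercept,
                    k_gs = k_gs, k_A = k_A, lam = lam,
                    SD_ab = SD_ab, SD_ad = SD_ad, gcl = gcl, pore = pore,
                    noise_A = noise_A, noise_gs = noise_gs)
  stopifnot(out$phi > 0, out$Amax > 0, out$Rd >= 0, out$k_gs > 0,
            out$k_A > 0, out$lam >= 0, out$pore < out$gcl)
  class(out) <- c("accession_truth", "data.frame")
  out
}

#' Draw a synthetic accession panel
#'
#' Draws `n_accessions` ground-truth parameter sets from the ranges in
#' `config` (see [panel_config()]) and replicates each over `n_plants`
#' plants. The A and gs time constants are drawn with a Gaussian copula so
#' their cross-accession correlation approximates `config$tau_rho`; the
#' per-accession coupling line is constructed through the panel anchor so
#' the panel-level Asat-gssat relation is tight by design.
#'
#' @param n_accessions,n_plants Panel dimensions.
#' @param seed Integer seed; identical seeds give identical panels.
#' @param config A [panel_config()].
#' @return Data frame of class `"accession_panel"`, one row per
#'   accession x plant, columns as in [accession_truth()].
#' @export
sample_panel <- function(n_accessions = 43, n_plants = 4, seed,
                         config = panel_config()) {
  stopifnot(n_accessions >= 1, n_plants >= 1)
  with_seed(seed, {
    runif_r <- function(r, n) stats::runif(n, r[1L], r[2L])
    n <- n_accessions
    phi <- runif_r(config$phi, n)
    Amax <- runif_r(config$Amax, n)
    Rd <- runif_r(config$Rd, n)
    Asat <- light_response_curve(2000, phi, Amax, Rd)
    eps <- pmin(pmax(stats::rnorm(n, 0, config$gssat_cv), -3 * config$gssat_cv),
                3 * config$gssat_cv)
    gssat <- (Asat - config$anchor_intercept) / config$anchor_slope * (1 + eps)
    b <- runif_r(config$coupling_slope, n)
    a <- Asat - b * gssat
    # Gaussian copula for correlated log-uniform time constants
    rho_z <- .calibrate_copula_rho(config$tau_rho, config$k_A, config$k_gs)
    z1 <- stats::rnorm(n)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n)
    lu <- function(z, r) exp(log(r[1L]) + stats::pnorm(z) * (log(r[2L]) - log(r[1L])))
    k_A <- lu(z1, config$k_A)
    k_gs <- lu(z2, config$k_gs)
    lam <- runif_r(config$lam, n)
    SD_ab <- runif_r(config$SD_ab, n)
    SD_ad <- runif_r(config$SD_ad, n)
    gcl <- runif_r(config$gcl, n)
    pore <- gcl * runif_r(config$pore_frac, n)
    acc <- sprintf("ACC%03d", seq_len(n))
    one <- data.frame(accession = acc, phi = phi, Amax = Amax, Rd = Rd,
                      coupling_slope = b, coupling_intercept = a,
                      k_gs = k_gs, k_A = k_A, lam = lam,
                      SD_ab = SD_ab, SD_ad = SD_ad, gcl = gcl, pore = pore,
                      noise_A = config$noise_A, noise_gs = config$noise_gs)
    panel <- one[rep(seq_len(n), each = n_plants), ]
    panel$plant_id <- paste0(panel$accession, "_p",
                             rep(seq_len(n_plants), times = n))
    rownames(panel) <- NULL
    panel <- panel[, c("accession", "plant_id",
                       setdiff(names(panel), c("accession", "plant_id")))]
    class(panel) <- c("accession_panel", "data.frame")
    panel
  })
}

# Find the Gaussian-copula parameter whose induced Pearson correlation
# between the two log-uniform time constants equals the requested rho.
# Log-uniform marginals attenuate the copula correlation, so the parameter
# is solved by root-finding on a fixed-seed Monte Carlo estimate (common
# random numbers keep the objective smooth and monotone).
.calibrate_copula_rho <- function(rho, range_A, range_gs, n = 50000L) {
  if (rho == 0) return(0)
  lu <- function(z, r) exp(log(r[1L]) + stats::pnorm(z) * (log(r[2L]) - log(r[1L])))
  mc <- with_seed(990001L, {
    z1 <- stats::rnorm(n); e <- stats::rnorm(n)
    function(rz) {
      z2 <- rz * z1 + sqrt(1 - rz^2) * e
      stats::cor(lu(z1, range_A), lu(z2, range_gs))
    }
  })
  lo <- max(-0.999, rho - 0.05)
  hi <- min(0.999, rho + 0.35)
  if (mc(hi) < rho) return(hi)
  stats::uniroot(function(rz) mc(rz) - rho, c(lo, hi), tol = 1e-4)$root
}

# target Ci/Ca as a function of PPFD: constant near the configured target at
# high light, relaxing toward 1 below 250 umol m^-2 s^-1 where assimilation
# no longer draws Ci down
.ci_ca_profile <- function(Q, target = 0.30) {
  target + (1 - target) * pmax(0, 1 - Q / 250)^1.5
}

#' Simulate a steady-state light-response measurement
#'
#' Emulates the 12-step A/Q protocol: PPFD decreasing through 2000, 1500,
#' 1250, 1000, 750, 500, 300, 200, 100, 50, 20, 0 umol m^-2 s^-1 with three
#' steady-state records per level (10 s apart, one level per 3 min). A
#' follows the accession's rectangular hyperbola plus Gaussian noise; gs is
#' derived from the noiseless A through the inverted coupling line (plus
#' its own noise, floored at 0.005 mol m^-2 s^-1); Ci is back-filled so
#' Ci/Ca sits near the configured target above 250 umol m^-2 s^-1 and
#' relaxes toward Ca below; Ca is the 400 umol mol^-1 set-point.
#'
#' @param truth One row of an [accession_truth()] / [sample_panel()].
#' @param seed Integer seed.
#' @param noise Set `FALSE` for noiseless output (exact round trips).
#' @param levels Nominal PPFD levels, in measurement order.
#' @param n_per_level Records per level.
#' @param ci_ca_target Target Ci/Ca at saturating light.
#' @return A [gasx_series()] with protocol `"light_curve"`.
#' @export
simulate_light_curve <- function(truth, seed, noise = TRUE,
                                 levels = c(2000, 1500, 1250, 1000, 750, 500,
                                            300, 200, 100, 50, 20, 0),
                                 n_per_level = 3, ci_ca_target = 0.30) {
  truth <- as.list(truth[1L, ])
  with_seed(seed, {
    nl <- length(levels)
    Q <- rep(levels, each = n_per_level)
    t <- as.numeric(180 * rep(seq_len(nl) - 1L, each = n_per_level) +
                    180 - 10 * (n_per_level - rep(seq_len(n_per_level), nl)))
    A_clean <- light_response_curve(Q, truth$phi, truth$Amax, truth$Rd)
    gs_clean <- pmax((A_clean - truth$coupling_intercept) / truth$coupling_slope,
                     0.005)
    if (noise) {
      A <- A_clean + stats::rnorm(length(Q), 0, truth$noise_A)
      gs <- pmax(gs_clean + stats::rnorm(length(Q), 0, truth$noise_gs), 0.005)
      jit <- pmin(pmax(stats::rnorm(nl, 0, 0.01), -0.025), 0.025)
      ratio <- pmin(.ci_ca_profile(levels, ci_ca_target) + jit, 1)
    } else {
      A <- A_clean
      gs <- gs_clean
      ratio <- pmin(.ci_ca_profile(levels, ci_ca_target), 1)
    }
    Ci <- rep(ratio, each = n_per_level) * 400
    gasx_series(plant_id = truth$plant_id, accession = truth$accession,
                protocol = "light_curve", t = t, Q = Q, A = A, gs = gs,
                Ci = Ci, Ca = rep(400, length(Q)))
  })
}

#' Simulate a step-change (induction) measurement
#'
#' Emulates the dynamic protocol: 5 min of 10 s samples at a PPFD of 100
#' umol m^-2 s^-1 (30 baseline records, t = 0..290 s), then a step to 1000
#' umol m^-2 s^-1 with 10 s sampling for 30 min (181 records,
#' t = 300..2100 s; 211 records in total). Steady values at each light
#' level come from the accession's light-response and coupling truths; the
#' post-step time courses of A and gs follow the sigmoidal induction model
#' with the accession's time constants (`k_A`, `k_gs`) and shared lag.
#'
#' @inheritParams simulate_light_curve
#' @param dt Sampling interval, s.
#' @param t_baseline,t_response Phase durations, s.
#' @param Q_low,Q_high PPFD levels, umol m^-2 s^-1.
#' @return A [gasx_series()] with protocol `"step_change"`.
#' @export
simulate_step_response <- function(truth, seed, noise = TRUE, dt = 10,
                                   t_baseline = 300, t_response = 1800,
                                   Q_low = 100, Q_high = 1000,
                                   ci_ca_target = 0.30) {
  truth <- as.list(truth[1L, ])
  with_seed(seed, {
    t_base <- seq(0, t_baseline - dt, by = dt)
    t_resp <- seq(t_baseline, t_baseline + t_response, by = dt)
    t <- c(t_base, t_resp)
    Q <- c(rep(Q_low, length(t_base)), rep(Q_high, length(t_resp)))
    A0 <- light_response_curve(Q_low, truth$phi, truth$Amax, truth$Rd)
    Af <- light_response_curve(Q_high, truth$phi, truth$Amax, truth$Rd)
    gs0 <- (A0 - truth$coupling_intercept) / truth$coupling_slope
    gsf <- (Af - truth$coupling_intercept) / truth$coupling_slope
    tp <- t_resp - t_baseline
    A <- c(rep(A0, length(t_base)),
           induction_curve(tp, A0, Af, truth$lam, truth$k_A))
    gs <- c(rep(gs0, length(t_base)),
            induction_curve(tp, gs0, gsf, truth$lam, truth$k_gs))
    if (noise) {
      A <- A + stats::rnorm(length(t), 0, truth$noise_A)
      gs <- pmax(gs + stats::rnorm(length(t), 0, truth$noise_gs), 0)
      jit <- stats::rnorm(length(t), 0, 0.005)
    } else {
      jit <- 0
    }
    ratio <- pmin(pmax(.ci_ca_profile(Q, ci_ca_target) + jit, 0.05), 1)
    gasx_series(plant_id = truth$plant_id, accession = truth$accession,
                protocol = "step_change", t = t, Q = Q, A = A, gs = gs,
                Ci = ratio * 400, Ca = rep(400, length(t)))
  })
}

#' Simulate stomatal anatomy records
#'
#' Emulates impression microscopy of both leaf surfaces: per plant and
#' surface, `n_fields` fields of view with stomatal counts drawn
#' Poisson(SD x field area), and one guard-cell/pore length measurement per
#' field drawn Normal around the accession truth with 5% CV, truncated
#' positive and with pore < guard cell length enforced.
#'
#' @param truth One accession truth row.
#' @param n_plants Number of plants to emit (default 6).
#' @param n_fields Fields of view (= geometry measurements) per plant and
#'   surface (default 9).
#' @param seed Integer seed.
#' @param field_area_mm2 Field-of-view area, mm^2.
#' @param plant_ids Optional explicit plant identifiers (length
#'   `n_plants`).
#' @return An [anatomy_records()] data frame.
#' @export
simulate_anatomy <- function(truth, n_plants = 6, n_fields = 9, seed,
                             field_area_mm2 = 0.29, plant_ids = NULL) {
  truth <- as.list(truth[1L, ])
  stopifnot(n_plants >= 1, n_fields >= 1)
  if (is.null(plant_ids))
    plant_ids <- paste0(truth$accession, "_p", seq_len(n_plants))
  stopifnot(length(plant_ids) == n_plants)
  with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_plants)) for (surf in c("abaxial", "adaxial")) {
      SD <- if (surf == "abaxial") truth$SD_ab else truth$SD_ad
      counts <- stats::rpois(n_fields, SD * field_area_mm2)
      gcl <- pmax(stats::rnorm(n_fields, truth$gcl, 0.05 * truth$gcl),
                  0.2 * truth$gcl)
      pore <- pmax(stats::rnorm(n_fields, truth$pore, 0.05 * truth$pore),
                   0.2 * truth$pore)
      pore <- pmin(pore, 0.95 * gcl)
      rows[[length(rows) + 1L]] <-
        data.frame(plant_id = plant_ids[p], accession = truth$accession,
                   surface = surf, field_count = counts,
                   field_area_mm2 = field_area_mm2,
                   gcl_um = gcl, pore_um = pore)
    }
    anatomy_records(do.call(rbind, rows))
  })
}

# deterministic per-plant sub-seeds below 2^31
.derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate all measurements for a panel
#'
#' Runs the three generators for every plant of a panel, with per-plant
#' seeds derived deterministically from `seed`.
#'
#' @param panel A [sample_panel()] result.
#' @param seed Integer master seed.
#' @param noise Passed to the gas-exchange generators.
#' @param n_fields Fields of view per plant and surface.
#' @param field_area_mm2 Field-of-view area, mm^2.
#' @return A list with `light` (list of `gasx_series`), `step` (list of
#'   `gasx_series`), `anatomy` (one `anatomy_records` data frame) and
#'   `truths` (the panel).
#' @export
simulate_panel <- function(panel, seed, noise = TRUE, n_fields = 9,
                           field_area_mm2 = 0.29) {
  n <- nrow(panel)
  seeds <- .derive_seeds(seed, 3L * n)
  light <- vector("list", n)
  step <- vector("list", n)
  anat <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- panel[i, ]
    light[[i]] <- simulate_light_curve(tr, seed = seeds[i], noise = noise)
    step[[i]] <- simulate_step_response(tr, seed = seeds[n + i], noise = noise)
    anat[[i]] <- simulate_anatomy(tr, n_plants = 1L, n_fields = n_fields,
                                  seed = seeds[2L * n + i],
                                  field_area_mm2 = field_area_mm2,
                                  plant_ids = tr$plant_id)
  }
  names(light) <- names(step) <- panel$plant_id
  list(light = light, step = step,
       anatomy = anatomy_records(do.call(rbind, anat)), truths = panel)
}

#' Write a simulated panel to disk
#'
#' Emits the file layout the readers consume: `gasx/light/<plant>.csv` and
#' `gasx/step/<plant>.csv` (comma-separated gas-exchange logs),
#' `anatomy.tsv`, and `truths.tsv` for recovery scoring. Output is
#' deterministic: identical panels produce byte-identical files.
#'
#' @param sim A [simulate_panel()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  for (d in file.path(out_dir, c("gasx/light", "gasx/step")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sim$light))
    write_gasx_table(sim$light[[i]],
                     file.path(out_dir, "gasx", "light",
                               paste0(names(sim$light)[i], ".csv")), sep = ",")
  for (i in seq_along(sim$step))
    write_gasx_table(sim$step[[i]],
                     file.path(out_dir, "gasx", "step",
                               paste0(names(sim$step)[i], ".csv")), sep = ",")
  utils::write.table(format(as.data.frame(sim$anatomy), digits = 17,
                            trim = TRUE, scientific = FALSE),
                     file.path(out_dir, "anatomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(format(as.data.frame(sim$truths), digits = 17,
                            trim = TRUE, scientific = FALSE),
                     file.path(out_dir, "truths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read a dataset directory written by write_dataset
#'
#' @param dir Directory with `gasx/light/*.csv`, `gasx/step/*.csv`,
#'   `anatomy.tsv` and optionally `truths.tsv`.
#' @return A list shaped like a [simulate_panel()] result (`truths` is
#'   `NULL` when absent).
#' @export
read_dataset <- function(dir) {
  read_all <- function(sub, protocol) {
    files <- sort(list.files(file.path(dir, "gasx", sub), full.names = TRUE))
    out <- list()
    for (f in files) out <- c(out, read_gasx_table(f, protocol = protocol))
    out
  }
  light <- read_all("light", "light_curve")
  step <- read_all("step", "step_change")
  anatomy_path <- file.path(dir, "anatomy.tsv")
  truths_path <- file.path(dir, "truths.tsv")
  list(light = light, step = step,
       anatomy = if (file.exists(anatomy_path)) read_anatomy_table(anatomy_path),
       truths = if (file.exists(truths_path))
         utils::read.table(truths_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE))
}
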