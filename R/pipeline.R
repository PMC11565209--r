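#' Pipeline run configuration
#'
#' Describes one end-to-end run: either a `simulate` block (panel
#' dimensions drawn by the generator) or an `input_dir` with measured
#' files, plus the analysis settings. Exactly one data source must be
#' given.
#'
#' @param simulate `NULL`, or a list with `n_accessions`, `n_plants` and
#'   optionally a [panel_config()] as `config` and `noise`.
#' @param input_dir `NULL`, or a dataset directory laid out as written by
#'   [write_dataset()].
#' @param seed Integer seed governing all randomness of the run.
#' @param alpha Significance level for the panel statistics, in (0, 0.5].
#' @param constants [gasx_constants()] used for anatomical gsmax.
#' @param eps_gs Conductance floor for Wi, mol m^-2 s^-1.
#' @param out_dir Optional output directory for the TSV tables.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(simulate = list(n_accessions = 43, n_plants = 4),
                       input_dir = NULL, seed = 1, alpha = 0.05,
                       constants = gasx_constants(), eps_gs = 0.005,
                       out_dir = NULL) {
  if (is.null(simulate) == is.null(input_dir))
    stop("exactly one of `simulate` or `input_dir` must be given", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 0.5)
  structure(list(simulate = simulate, input_dir = input_dir, seed = seed,
                 alpha = alpha, constants = constants, eps_gs = eps_gs,
                 out_dir = out_dir),
            class = "run_config")
}

# hash of the scientific part of the config (output location excluded)
.config_hash <- function(config) {
  core <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(core), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(stage, plant, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for plant %s: %s", stage, plant,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full trait-extraction pipeline
#'
#' Orchestrates simulate (or read) -> light-response fits -> induction fits
#' -> Wi steady states -> anatomy -> panel statistics. Produces a per-plant
#' trait table, per-accession means, ANOVA tables with Tukey compact
#' letters per trait, a correlation matrix across accession means, and a
#' run manifest. The run is a pure function of (config, input files): the
#' same config yields byte-identical output tables.
#'
#' @param config A [run_config()].
#' @return A list of class `"gasx_run"` with `traits`, `accession_means`,
#'   `anova`, `letters`, `correlations`, `manifest`, and the input `data`.
#'   Tables are also written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    panel <- sample_panel(n_accessions = sim_args$n_accessions,
                          n_plants = sim_args$n_plants, seed = config$seed,
                          config = if (!is.null(sim_args$config)) sim_args$config
                                   else panel_config())
    data <- simulate_panel(panel, seed = config$seed,
                           noise = !isFALSE(sim_args$noise))
  } else {
    data <- read_dataset(config$input_dir)
  }

  plants <- sort(unique(vapply(data$light, attr, "", "plant_id")))
  gsx <- gsmax_from_anatomy(data$anatomy, config$constants)
  traits <- do.call(rbind, lapply(plants, function(p) {
    ls <- data$light[[which(vapply(data$light, attr, "", "plant_id") == p)[1L]]]
    ss <- data$step[[which(vapply(data$step, attr, "", "plant_id") == p)[1L]]]
    acc <- attr(ls, "accession")
    fitL <- .stage("fit_light", p, fit_light_response(ls))
    sumL <- .stage("summarize_light", p, summarize_light_curve(ls, fitL))
    ph <- .stage("split_step", p, split_step(ss))
    fitA <- .stage("fit_induction_A", p, fit_induction(ph, "A"))
    fitG <- .stage("fit_induction_gs", p, fit_induction(ph, "gs"))
    wi <- .stage("steady_state_wi", p,
                 steady_state_wi(ph, eps_gs = config$eps_gs))
    surf <- gsx$surfaces[gsx$surfaces$plant_id == p, ]
    leaf <- gsx$leaves[gsx$leaves$plant_id == p, ]
    pick <- function(side, col) {
      v <- surf[[col]][surf$surface == side]
      if (length(v)) v else NA_real_
    }
    data.frame(accession = acc, plant_id = p,
               QY = sumL$QY, Asat = sumL$Asat, gssat = sumL$gssat,
               Rd = sumL$Rd, sse_light = sumL$sse,
               tau_ai = fitA$tau, tau_i = fitG$tau,
               lam_a = unname(coef(fitA)[["lam"]]),
               lam_gs = unname(coef(fitG)[["lam"]]),
               A0 = unname(coef(fitA)[["y0"]]), Af = unname(coef(fitA)[["yf"]]),
               gs0 = unname(coef(fitG)[["y0"]]), gsf = unname(coef(fitG)[["yf"]]),
               Wi_low = wi$Wi_low, Wi_high = wi$Wi_high,
               SD_ab = pick("abaxial", "SD_mm2"),
               SD_ad = pick("adaxial", "SD_mm2"),
               gsmax_ab = pick("abaxial", "gsmax"),
               gsmax_ad = pick("adaxial", "gsmax"),
               gsmax_leaf = if (nrow(leaf)) leaf$gsmax_leaf else NA_real_,
               flag_no_response_A = fitA$no_response,
               flag_no_response_gs = fitG$no_response)
  }))
  rownames(traits) <- NULL

  trait_cols <- c("QY", "Asat", "gssat", "Rd", "tau_ai", "tau_i",
                  "Wi_low", "Wi_high", "SD_ab", "SD_ad",
                  "gsmax_ab", "gsmax_ad", "gsmax_leaf")
  acc_means <- stats::aggregate(traits[trait_cols],
                                by = list(accession = traits$accession),
                                FUN = mean, na.rm = TRUE)
  acc_means <- acc_means[order(acc_means$accession), ]
  rownames(acc_means) <- NULL

  multi_rep <- any(table(traits$accession) > 1L)
  anova_rows <- list(); letter_rows <- list()
  if (multi_rep && length(unique(traits$accession)) >= 2L) {
    for (tc in trait_cols) {
      v <- traits[[tc]]
      ok <- is.finite(v)
      if (sum(ok) < 4L || length(unique(traits$accession[ok])) < 2L) next
      at <- anova_table(v[ok], traits$accession[ok])
      at$trait <- tc
      anova_rows[[tc]] <- at
      p_acc <- at$p[at$term == "f1"]
      if (is.finite(p_acc) && p_acc <= config$alpha) {
        th <- tukey_hsd(v[ok], traits$accession[ok], alpha = config$alpha)
        letter_rows[[tc]] <- data.frame(trait = tc, accession = th$groups,
                                        mean = th$means,
                                        letters = unname(th$letters[th$groups]))
      } else {
        grp <- sort(unique(traits$accession[ok]))
        letter_rows[[tc]] <- data.frame(trait = tc, accession = grp,
                                        mean = acc_means[[tc]][match(grp, acc_means$accession)],
                                        letters = "a")
      }
    }
  }
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  letters_tab <- if (length(letter_rows)) do.call(rbind, letter_rows) else NULL
  if (!is.null(anova_tab)) rownames(anova_tab) <- NULL
  if (!is.null(letters_tab)) rownames(letters_tab) <- NULL

  cors <- NULL
  if (nrow(acc_means) >= 3L) {
    cc <- utils::combn(trait_cols, 2L)
    cors <- do.call(rbind, lapply(seq_len(ncol(cc)), function(i) {
      x <- acc_means[[cc[1L, i]]]; y <- acc_means[[cc[2L, i]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
        return(NULL)
      ct <- pearson(x[ok], y[ok])
      data.frame(trait_x = cc[1L, i], trait_y = cc[2L, i],
                 R = ct$R, p = ct$p, n = ct$n)
    }))
    if (!is.null(cors)) rownames(cors) <- NULL
  }

  manifest <- data.frame(
    key = c("package", "version", "r_version", "seed", "alpha",
            "config_hash", "n_plants_analysed", "n_accessions"),
    value = c("gasx", as.character(utils::packageVersion("gasx")),
              paste(R.version$major, R.version$minor, sep = "."),
              as.character(config$seed), as.character(config$alpha),
              .config_hash(config), as.character(nrow(traits)),
              as.character(length(unique(traits$accession)))))

  out <- structure(list(traits = traits, accession_means = acc_means,
                        anova = anova_tab, letters = letters_tab,
                        correlations = cors, manifest = manifest, data = data),
                   class = "gasx_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' Write pipeline output tables
#'
#' @param run A `"gasx_run"` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(format(df, digits = 15, trim = TRUE),
                       file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(run$traits, "traits.tsv")
  wt(run$accession_means, "accession_means.tsv")
  wt(run$anova, "anova.tsv")
  wt(run$letters, "letters.tsv")
  wt(run$correlations, "correlations.tsv")
  wt(run$manifest, "manifest.tsv")
  invisible(out_dir)
}

#' @export
print.gasx_run <- function(x, ...) {
  cat(sprintf("<gasx_run> %d plants, %d accessions\n", nrow(x$traits),
              length(unique(x$traits$accession))))
  cat("Per-plant traits (head):\n")
  print(utils::head(x$traits[, c("accession", "plant_id", "QY", "Asat",
                                 "gssat", "tau_ai", "tau_i", "Wi_low",
                                 "Wi_high", "gsmax_leaf")], 5L), digits = 4)
  invisible(x)
}

#' Score trait recovery against generator truths
#'
#' Joins estimated per-plant traits to the generator's ground truths and
#' reports relative errors for the parameters the pipeline estimates
#' directly: quantum yield, the two time constants, and the two surface
#' stomatal densities.
#'
#' @param traits Trait table from [run_pipeline()].
#' @param truths Truth table (panel rows or `truths.tsv` contents).
#' @param tolerances Named relative-error tolerances used for the
#'   `within_tol` flags.
#' @return Data frame with one row per plant x parameter: `plant_id`,
#'   `parameter`, `truth`, `estimate`, `rel_err`, `within_tol`.
#' @export
recover_truths <- function(traits, truths,
                           tolerances = c(QY = 0.10, tau_ai = 0.15,
                                          tau_i = 0.15, SD_ab = 0.20,
                                          SD_ad = 0.20)) {
  map <- c(QY = "phi", tau_ai = "k_A", tau_i = "k_gs",
           SD_ab = "SD_ab", SD_ad = "SD_ad")
  j <- merge(traits, truths, by = "plant_id", suffixes = c("", ".truth"))
  out <- do.call(rbind, lapply(names(map), function(est) {
    tru_col <- if (paste0(map[[est]], ".truth") %in% names(j))
      paste0(map[[est]], ".truth") else map[[est]]
    tru <- j[[tru_col]]
    estv <- j[[est]]
    data.frame(plant_id = j$plant_id, parameter = est, truth = tru,
               estimate = estv, rel_err = (estv - tru) / tru,
               within_tol = abs((estv - tru) / tru) <= tolerances[[est]])
  }))
  rownames(out) <- NULL
  out
}
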