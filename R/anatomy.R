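#' Stomatal density per plant and leaf surface
#'
#' Pools counted fields of view within each (plant, surface): density is the
#' total count divided by the total sampled area, in mm^-2 and m^-2. Also
#' returns per-accession surface means of the plant densities.
#'
#' @param records An [anatomy_records()] data frame (per-field rows).
#' @return A list with `plants` (plant_id, accession, surface, n_fields,
#'   SD_mm2, SD_m2) and `accessions` (accession, surface, SD_mm2 mean over
#'   plants).
#' @export
stomatal_density <- function(records) {
  records <- anatomy_records(as.data.frame(records))
  key <- interaction(records$plant_id, records$surface, drop = TRUE)
  plants <- do.call(rbind, lapply(split(records, key), function(g) {
    area <- sum(g$field_area_mm2)
    if (area <= 0) stop("zero total field area for plant ", g$plant_id[1L],
                        call. = FALSE)
    data.frame(plant_id = g$plant_id[1L], accession = g$accession[1L],
               surface = g$surface[1L], n_fields = nrow(g),
               SD_mm2 = sum(g$field_count) / area,
               SD_m2 = sum(g$field_count) / area * 1e6)
  }))
  rownames(plants) <- NULL
  acc <- stats::aggregate(SD_mm2 ~ accession + surface, data = plants, FUN = mean)
  list(plants = plants, accessions = acc)
}

#' Maximal stomatal pore area from pore length
#'
#' Models the fully open stomatal pore as an ellipse whose major axis equals
#' the pore length and whose minor axis is half the pore length, i.e.
#' semi-axes p/2 and p/4, giving `a_max = pi * p^2 / 8`, returned in m^2.
#'
#' @param pore_length_um Stomatal pore length, micrometres, > 0.
#' @return Maximal pore area, m^2.
#' @examples
#' pore_area_max(20)  # 1.5708e-10 m^2 = 157.08 um^2
#' @export
pore_area_max <- function(pore_length_um) {
  if (any(!is.finite(pore_length_um)) || any(pore_length_um <= 0))
    stop("pore length must be a positive finite number (um)", call. = FALSE)
  pi * (pore_length_um * 1e-6)^2 / 8
}

#' Anatomical maximum stomatal conductance of one leaf surface
#'
#' Diffusion-based theoretical maximum conductance to water vapour given the
#' stomatal density and fully open pore geometry of one surface:
#' \deqn{g_{smax} = \frac{d\, SD\, a_{max}}{v\,\big(l + \frac{\pi}{2}\sqrt{a_{max}/\pi}\big)}}
#' with `a_max` the elliptical maximal pore area ([pore_area_max()]) and
#' pore depth `l` taken as a quarter of the guard cell length. All terms in
#' SI units; the result is in mol m^-2 s^-1.
#'
#' @param SD Stomatal density in m^-2. Densities below 1e6 m^-2 almost
#'   certainly mean a value in mm^-2 was passed and raise an error with a
#'   conversion hint.
#' @param pore_length_um Stomatal pore length, micrometres.
#' @param guard_cell_length_um Guard cell length, micrometres.
#' @param consts A [gasx_constants()] object.
#' @param surface Optional surface label carried into the result.
#' @return A list of class `"gsmax_result"`: `surface`, `SD` (m^-2),
#'   `a_max` (m^2), `pore_depth_l` (m), `gsmax` (mol m^-2 s^-1). All inputs
#'   may be vectors of equal length, in which case each field is a vector.
#' @examples
#' anatomical_gsmax(SD = 100e6, pore_length_um = 20, guard_cell_length_um = 40)
#' @export
anatomical_gsmax <- function(SD, pore_length_um, guard_cell_length_um,
                             consts = gasx_constants(), surface = NA_character_) {
  stopifnot(inherits(consts, "gasx_constants"))
  if (any(!is.finite(SD)) || any(SD <= 0))
    stop("SD must be positive and finite (m^-2)", call. = FALSE)
  if (any(SD < 1e6))
    stop("SD < 1e6 m^-2: this looks like a density in mm^-2; multiply by 1e6",
         call. = FALSE)
  if (any(guard_cell_length_um <= 0))
    stop("guard cell length must be > 0 (um)", call. = FALSE)
  a_max <- pore_area_max(pore_length_um)
  l <- guard_cell_length_um / 4 * 1e-6
  gsmax <- (consts$d * SD * a_max) / (consts$v * (l + (pi / 2) * sqrt(a_max / pi)))
  structure(list(surface = surface, SD = SD, a_max = a_max, pore_depth_l = l,
                 gsmax = gsmax),
            class = "gsmax_result")
}

#' @export
print.gsmax_result <- function(x, ...) {
  cat(sprintf("Anatomical gsmax (%s): %s mol m-2 s-1\n",
              paste(x$surface, collapse = ","),
              paste(signif(x$gsmax, 5), collapse = ", ")))
  cat(sprintf("  SD = %s m-2, a_max = %s m^2, pore depth = %s m\n",
              paste(signif(x$SD, 4), collapse = ","),
              paste(signif(x$a_max, 4), collapse = ","),
              paste(signif(x$pore_depth_l, 4), collapse = ",")))
  invisible(x)
}

#' Leaf-level anatomical gsmax from the two surfaces
#'
#' Stomata on the two leaf surfaces act as parallel diffusion pathways, so
#' the whole-leaf anatomical maximum conductance is the sum of the abaxial
#' and adaxial surface values.
#'
#' @param ab,ad Abaxial and adaxial values: either `"gsmax_result"` objects
#'   or bare numerics (mol m^-2 s^-1). Both must be present.
#' @return Leaf-level gsmax, mol m^-2 s^-1.
#' @export
leaf_gsmax <- function(ab, ad) {
  val <- function(x, side) {
    if (inherits(x, "gsmax_result")) x <- x$gsmax
    if (is.null(x) || length(x) == 0L || any(is.na(x)))
      stop(sprintf("missing %s surface gsmax", side), call. = FALSE)
    x
  }
  val(ab, "abaxial") + val(ad, "adaxial")
}

#' Per-plant anatomical gsmax from raw anatomy records
#'
#' Convenience wrapper: pools field counts into a plant-surface density,
#' averages the measured guard cell and pore lengths per plant-surface, and
#' applies [anatomical_gsmax()] to the mean geometry (geometry is averaged
#' before the equation, not per stoma). Plants with both surfaces also get
#' the leaf-level sum.
#'
#' @param records An [anatomy_records()] data frame with `gcl_um` and
#'   `pore_um` present.
#' @param consts A [gasx_constants()].
#' @return A list with `surfaces` (per plant-surface data frame incl.
#'   `gsmax`) and `leaves` (per plant data frame with `gsmax_leaf`).
#' @export
gsmax_from_anatomy <- function(records, consts = gasx_constants()) {
  records <- anatomy_records(as.data.frame(records))
  if (is.null(records$gcl_um) || is.null(records$pore_um))
    stop("records must include gcl_um and pore_um for gsmax", call. = FALSE)
  dens <- stomatal_density(records)$plants
  geo <- stats::aggregate(cbind(gcl_um, pore_um) ~ plant_id + surface,
                          data = records, FUN = mean)
  surf <- merge(dens, geo, by = c("plant_id", "surface"))
  gr <- anatomical_gsmax(surf$SD_m2, surf$pore_um, surf$gcl_um, consts,
                         surface = surf$surface)
  surf$a_max <- gr$a_max
  surf$gsmax <- gr$gsmax
  surf <- surf[order(surf$plant_id, surf$surface), ]
  rownames(surf) <- NULL
  leaves <- do.call(rbind, lapply(split(surf, surf$plant_id), function(g) {
    if (!all(c("abaxial", "adaxial") %in% g$surface)) return(NULL)
    data.frame(plant_id = g$plant_id[1L], accession = g$accession[1L],
               gsmax_leaf = leaf_gsmax(g$gsmax[g$surface == "abaxial"],
                                       g$gsmax[g$surface == "adaxial"]))
  }))
  if (!is.null(leaves)) rownames(leaves) <- NULL
  list(surfaces = surf, leaves = leaves)
}
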