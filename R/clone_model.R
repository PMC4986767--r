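#' Assumptions for clone-size estimation
#'
#' Converts an allele fraction measured in bulk DNA into the size of the
#' clonal patch carrying the variant, for a cellular monolayer such as the
#' lens epithelium. Defaults: a diploid heterozygous variant, a total
#' epithelium of 0.5e6 cells, the whole epithelium sampled, and a cell
#' density of 5500 cells per square millimetre (peripheral lens
#' epithelium).
#'
#' @param zygosity `"heterozygous"` (one variant allele per mutant cell) or
#'   `"homozygous"` (both alleles).
#' @param cells_total_epithelium Total cells in the epithelium.
#' @param sampled_area_fraction Fraction of the epithelial area contained
#'   in the sampled specimen, in (0, 1\]. Cells are assumed uniformly
#'   distributed over the area.
#' @param cell_density Cells per square millimetre.
#' @return A `clone_assumptions` list.
#' @export
clone_assumptions <- function(zygosity = c("heterozygous", "homozygous"),
                              cells_total_epithelium = 0.5e6,
                              sampled_area_fraction = 1,
                              cell_density = 5500) {
  zygosity <- match.arg(zygosity)
  stopifnot(cells_total_epithelium > 0,
            sampled_area_fraction > 0, sampled_area_fraction <= 1,
            cell_density > 0)
  structure(list(zygosity = zygosity,
                 cells_total_epithelium = cells_total_epithelium,
                 sampled_area_fraction = sampled_area_fraction,
                 cell_density = cell_density),
            class = "clone_assumptions")
}

#' Fraction of sampled cells carrying a variant
#'
#' In a diploid tissue a heterozygous variant contributes one of two
#' alleles per mutant cell, so the mutant-cell fraction is twice the
#' variant allele fraction (capped at 1); a homozygous variant contributes
#' both alleles and the cell fraction equals the allele fraction.
#'
#' @param vaf Variant allele fraction in \[0, 1\].
#' @param zygosity `"heterozygous"` or `"homozygous"`.
#' @return The fraction of cells carrying the variant, in \[0, 1\].
#' @examples
#' cell_fraction(0.01, "heterozygous")  # 0.02
#' @export
cell_fraction <- function(vaf, zygosity = c("heterozygous", "homozygous")) {
  zygosity <- match.arg(zygosity)
  stopifnot(all(vaf >= 0), all(vaf <= 1))
  if (zygosity == "heterozygous") pmin(1, 2 * vaf) else vaf
}

#' Number of cells in the mutant clone
#'
#' The clone's cell count is the mutant-cell fraction applied to the number
#' of cells in the sampled specimen (total epithelium times the sampled
#' area fraction), rounded to the nearest cell.
#'
#' @param fraction Mutant-cell fraction in \[0, 1\].
#' @param assumptions A [clone_assumptions()].
#' @return Integer-valued cell count.
#' @examples
#' clone_cells(0.02, clone_assumptions(sampled_area_fraction = 0.5))  # 5000
#' @export
clone_cells <- function(fraction, assumptions = clone_assumptions()) {
  stopifnot(inherits(assumptions, "clone_assumptions"),
            all(fraction >= 0), all(fraction <= 1))
  round(fraction * assumptions$cells_total_epithelium *
          assumptions$sampled_area_fraction)
}

#' Area covered by the mutant clone
#'
#' With cells distributed uniformly at `density` cells per square
#' millimetre, a clone of `clone_cells` cells covers
#' `clone_cells / density` square millimetres.
#'
#' @param clone_cells Number of cells in the clone.
#' @param density Cells per square millimetre.
#' @return Area in square millimetres (exact; see [estimate_clone()] for
#'   the companion rounded value).
#' @examples
#' clone_area(5000, 5500)  # 0.909... mm^2, i.e. about 1 mm^2
#' @export
clone_area <- function(clone_cells, density = 5500) {
  stopifnot(density > 0, all(clone_cells >= 0))
  clone_cells / density
}

#' Estimate clone size from a variant allele fraction
#'
#' Chains [cell_fraction()], [clone_cells()] and [clone_area()] under
#' explicit assumptions. The area is reported both exactly and rounded to
#' the nearest whole square millimetre, matching the coarse "about a square
#' millimetre" style in which such estimates are usually quoted.
#'
#' @param vaf Variant allele fraction in \[0, 1\].
#' @param assumptions A [clone_assumptions()].
#' @return A `clone_estimate` list: `vaf`, `zygosity`, `cell_fraction`,
#'   `cells_sampled`, `clone_cells`, `clone_area_mm2`,
#'   `clone_area_mm2_rounded`.
#' @examples
#' estimate_clone(0.01, clone_assumptions(sampled_area_fraction = 0.5))
#' @export
estimate_clone <- function(vaf, assumptions = clone_assumptions()) {
  stopifnot(inherits(assumptions, "clone_assumptions"))
  frac <- cell_fraction(vaf, assumptions$zygosity)
  cells_sampled <- assumptions$cells_total_epithelium *
    assumptions$sampled_area_fraction
  n_cells <- clone_cells(frac, assumptions)
  area <- clone_area(n_cells, assumptions$cell_density)
  structure(list(vaf = vaf, zygosity = assumptions$zygosity,
                 cell_fraction = frac,
                 cells_sampled = cells_sampled,
                 clone_cells = n_cells,
                 clone_area_mm2 = area,
                 clone_area_mm2_rounded = round(area)),
            class = "clone_estimate")
}

#' @export
print.clone_estimate <- function(x, ...) {
  cat("<clone_estimate>\n")
  cat(sprintf("  VAF %.4g (%s) -> %.3g%% of sampled cells\n",
              x$vaf, x$zygosity, 100 * x$cell_fraction))
  cat(sprintf("  %s cells sampled -> clone of %s cells\n",
              format(x$cells_sampled, big.mark = ","),
              format(x$clone_cells, big.mark = ",")))
  cat(sprintf("  clone area %.3g mm^2 (~%g mm^2)\n",
              x$clone_area_mm2, x$clone_area_mm2_rounded))
  invisible(x)
}
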