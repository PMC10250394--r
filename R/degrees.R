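#' Consanguinity degree parameter table
#'
#' Parameters of the block-inheritance (Clark) model for offspring of parents
#' related at degrees two through six:
#' \describe{
#'   \item{degree}{pedigree distance between the parents (2 = avuncular,
#'     3 = first cousins, 4 = first cousins once removed, 5 = second cousins,
#'     6 = half second cousins).}
#'   \item{G}{total number of generations in the inheritance path from the
#'     proband back to the shared ancestors, summed over both parental paths.
#'     Ancestry-block genetic lengths are Exponential with mean `100 / G` cM.}
#'   \item{F}{per-block autozygosity probability; equals the pedigree
#'     inbreeding coefficient of the offspring. For first cousins, 4 of the
#'     8 x 8 = 64 joint inheritance patterns are consanguineous, so
#'     F = 4/64 = 6.25\%. F halves with each additional degree.}
#' }
#'
#' @param degree optional integer vector in 2..6 to subset the table.
#' @return data.frame with columns `degree`, `label`, `G`, `F`.
#' @examples
#' consanguinity_degrees(3)   # first cousins: G = 6, F = 1/16
#' @export
consanguinity_degrees <- function(degree = NULL) {
  tab <- data.frame(
    degree = 2:6,
    label = c("second", "third", "fourth", "fifth", "unrelated"),
    G = c(5L, 6L, 7L, 8L, 8L),
    F = c(1 / 8, 1 / 16, 1 / 32, 1 / 64, 1 / 128),
    stringsAsFactors = FALSE
  )
  if (is.null(degree)) return(tab)
  if (!all(degree %in% tab$degree)) stop("degree must be in 2..6")
  tab[match(degree, tab$degree), , drop = FALSE]
}

#' First-cousin per-block autozygosity probability by enumeration
#'
#' Independent combinatorial check of the block model's F for offspring of
#' first cousins. At any autosomal locus the father transmits one of his 8
#' ancestral chromosomes three generations back, the mother one of her 8.
#' The parents, being first cousins, share one grandparental couple, i.e.
#' 4 of those 8 ancestral chromosomes are common to both sides. The locus is
#' autozygous exactly when both transmitted chromosomes are the same shared
#' ancestral chromosome. All 64 joint patterns are enumerated explicitly.
#'
#' @return the exact probability (4/64 = 0.0625) as a fraction.
#' @export
first_cousin_autozygosity_enumeration <- function() {
  shared <- c("A1", "A2", "B1", "B2")        # the shared grandparents' 4 chromosomes
  paternal <- c(shared, paste0("Pf", 1:4))   # plus 4 chromosomes private to the father's side
  maternal <- c(shared, paste0("Pm", 1:4))   # plus 4 private to the mother's side
  grid <- expand.grid(pat = paternal, mat = maternal, stringsAsFactors = FALSE)
  autozygous <- grid$pat == grid$mat
  sum(autozygous) / nrow(grid)
}
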