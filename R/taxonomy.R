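#' Retrotransposon class/family taxonomy
#'
#' The default taxonomy of repeat classes and the families they comprise, as
#' used throughout blood-cohort RTE analyses: LINE (L1, L2), SINE (Alu, MIR),
#' LTR (ERV1, ERVL, ERVL-MaLR, ERVK), plus Satellite DNA as a non-RTE control
#' class. Families belong to exactly one class.
#'
#' @param extra A named list mapping additional class names to character
#'   vectors of family names, merged into the default taxonomy.
#'
#' @return A tibble with columns `repeat_class` and `repeat_family`, one row
#'   per family, carrying an attribute `control_classes` (character vector,
#'   default `"Satellite"`).
#' @examples
#' rte_taxonomy()
#' @export
rte_taxonomy <- function(extra = NULL) {
  base <- list(
    LINE      = c("L1", "L2"),
    SINE      = c("Alu", "MIR"),
    LTR       = c("ERV1", "ERVL", "ERVL-MaLR", "ERVK"),
    Satellite = c("Satellite", "centr", "telo")
  )
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    for (cl in names(extra)) {
      base[[cl]] <- union(base[[cl]], extra[[cl]])
    }
  }
  fam <- unlist(base, use.names = FALSE)
  if (anyDuplicated(fam)) {
    stop("taxonomy invalid: family assigned to more than one class: ",
         paste(unique(fam[duplicated(fam)]), collapse = ", "))
  }
  out <- tibble::tibble(
    repeat_class  = rep(names(base), lengths(base)),
    repeat_family = fam
  )
  attr(out, "control_classes") <- "Satellite"
  out
}

#' RTE classes considered in the analyses
#'
#' @param include_control Include the Satellite control class?
#' @return Character vector of class labels.
#' @export
rte_classes <- function(include_control = FALSE) {
  cl <- c("LINE", "SINE", "LTR")
  if (include_control) cl <- c(cl, "Satellite")
  cl
}
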