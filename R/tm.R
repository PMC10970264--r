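## Nearest-neighbor duplex parameters (SantaLucia unified set): dH in
## kcal/mol, dS in cal/(mol K), 5'->3' top-strand dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT <- list(AT = c(dH = 2.3, dS = 4.1), GC = c(dH = 0.1, dS = -2.8))

#' Estimate a primer melting temperature
#'
#' Default model: nearest-neighbor thermodynamics with the unified
#' SantaLucia parameter set, 50 mM monovalent salt (entropy correction
#' 0.368 x (N-1) x ln[Na+]) and 200 nM primer in excess over template.
#' The Wallace 2+4 rule (\code{2(A+T) + 4(G+C)}) is available as a quick
#' alternative. Both are deterministic; the parameter table is fixed in
#' the package source.
#'
#' @param primer Primer sequence over \code{A,C,G,T}, length >= 8 for
#'   the nearest-neighbor model (>= 2 for Wallace).
#' @param method \code{"nn"} (default) or \code{"wallace"}.
#' @param Na Monovalent cation concentration in mM.
#' @param primerConc Primer concentration in nM.
#' @return Estimated melting temperature in degrees Celsius.
#' @export
estimateTm <- function(primer, method = c("nn", "wallace"), Na = 50,
                       primerConc = 200) {
  method <- match.arg(method)
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer) || !nzchar(primer))
    stopf("primer must be a non-empty sequence over {A,C,G,T}")
  b <- strsplit(primer, "")[[1L]]
  if (method == "wallace") {
    if (length(b) < 2L) stopf("primer too short")
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  }
  if (length(b) < 8L)
    stopf("nearest-neighbor model needs a primer of >= 8 nt")
  steps <- paste0(b[-length(b)], b[-1L])
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (term in b[c(1L, length(b))]) {
    init <- if (term %in% c("A", "T")) NN_INIT$AT else NN_INIT$GC
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  dS <- dS + 0.368 * (length(b) - 1L) * log(Na / 1000)
  R <- 1.987  # cal/(mol K)
  dH * 1000 / (dS + R * log(primerConc * 1e-9)) - 273.15
}
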