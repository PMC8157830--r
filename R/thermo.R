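# Primer composition and melting-temperature estimation.
#
# Diagnostic barcode regions are often AT-rich, so candidate primers are
# grown longer until the estimated Tm reaches the design window; these
# estimators back that loop. Two methods: the Wallace rule (2(A+T)+4(G+C),
# transparent on long AT-rich oligos) and unified nearest-neighbor
# thermodynamics with an entropic monovalent-salt correction.

# Unified NN stack parameters: dH (kcal/mol), dS (cal/(mol K)).
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT <- list(AT = c(dH = 2.3, dS = 4.1), GC = c(dH = 0.1, dS = -2.8))

#' Thermodynamic conditions for Tm estimation
#'
#' @param na_mM monovalent cation concentration, mM (> 0).
#' @param oligo_uM total primer concentration, micromolar (> 0).
#' @param method "nearest_neighbor" or "wallace".
#' @return a \code{thermo_conditions} list.
#' @export
thermo_conditions <- function(na_mM = 50, oligo_uM = 0.25,
                              method = c("nearest_neighbor", "wallace")) {
  method <- match.arg(method)
  if (na_mM <= 0 || oligo_uM <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  structure(list(na_mM = na_mM, oligo_uM = oligo_uM, method = method),
            class = "thermo_conditions")
}

check_unambiguous <- function(s, what = "sequence") {
  s <- normalize_dna(s, what = what)
  if (grepl("[^ACGT]", s)) {
    stop(what, " contains ambiguous bases; unambiguous A/C/G/T required",
         call. = FALSE)
  }
  s
}

#' GC fraction of an unambiguous DNA string
#'
#' @param s A/C/G/T string.
#' @return (#G + #C) / length, in [0, 1].
#' @examples
#' gc_content("GGCC") # 1
#' gc_content("ATAT") # 0
#' @export
gc_content <- function(s) {
  s <- check_unambiguous(s)
  chars <- split_chars(s)
  mean(chars %in% c("G", "C"))
}

tm_wallace <- function(s) {
  chars <- split_chars(s)
  2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
}

tm_nearest_neighbor <- function(s, na_mM, oligo_uM) {
  chars <- split_chars(s)
  n <- length(chars)
  stacks <- paste0(chars[-n], chars[-1])
  dH <- sum(NN_DH[stacks])
  dS <- sum(NN_DS[stacks])
  for (term in chars[c(1L, n)]) {
    init <- if (term %in% c("G", "C")) NN_INIT$GC else NN_INIT$AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  selfcomp <- identical(s, reverse_complement(s))
  ct <- oligo_uM * 1e-6
  if (selfcomp) {
    dS <- dS - 1.4
    x <- 1
  } else {
    x <- 4
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  R <- 1.9872
  1000 * dH / (dS + R * log(ct / x)) - 273.15
}

#' Primer melting temperature
#'
#' \code{wallace}: 2(A+T) + 4(G+C), in degrees C (concentration-independent).
#' \code{nearest_neighbor}: unified NN stack thermodynamics with the
#' 0.368 N ln[Na+] entropic salt correction and a CT/4 duplex-formation
#' term (CT/1 with a symmetry correction for self-complementary oligos).
#'
#' @param s unambiguous DNA string, 8-60 nt.
#' @param cond \code{\link{thermo_conditions}}.
#' @return estimated Tm in degrees C.
#' @examples
#' melting_temperature("ACGTACGT", thermo_conditions(method = "wallace"))
#' @export
melting_temperature <- function(s, cond = thermo_conditions()) {
  stopifnot(inherits(cond, "thermo_conditions"))
  s <- check_unambiguous(s)
  n <- nchar(s)
  if (n < 8 || n > 60) {
    stop("sequence length ", n, " outside the supported 8-60 nt range",
         call. = FALSE)
  }
  switch(cond$method,
         wallace = tm_wallace(s),
         nearest_neighbor = tm_nearest_neighbor(s, cond$na_mM, cond$oligo_uM))
}

#' Suggested annealing temperature for a primer pair
#'
#' The common min(Tm) - 5 degC heuristic; reported for guidance only, never
#' enforced. Bench optimization (e.g., gradient PCR) remains the authority.
#'
#' @param pair a \code{primer_pair}.
#' @param cond \code{\link{thermo_conditions}}.
#' @return suggested annealing temperature, degrees C.
#' @export
suggested_annealing <- function(pair, cond = thermo_conditions()) {
  min(melting_temperature(pair$forward$sequence, cond),
      melting_temperature(pair$reverse$sequence, cond)) - 5
}
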