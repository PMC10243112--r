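# Lipid shorthand -> elemental formula -> adduct m/z -> ppm error.
#
# Composition rules are assembled from building blocks:
#   acyl residue (c:d)      = fatty acid CcH(2c-2d)O2 minus H2O  (esterification)
#   glycerophospho head     = glycerol-3-phosphate + head-group alcohol
#   sphingoid "d" backbone  = 2 hydroxyls + 1 amine folded into the total
#                             carbon/double-bond count (Cer: CcH(2c-2d+1)NO3)
# Ether ("O-") linkage replaces one ester bond: -1 O, +2 H relative to diacyl.

MONOISOTOPIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

PROTON_MASS <- 1.007276

# mass deltas applied to the neutral monoisotopic mass M
ADDUCT_DELTAS <- c(
  "[M-H]-"          = -1.007276,
  "[M+CH3COOH-H]-"  = 59.013853,
  "[M+HCO2H-H]-"    = 44.998204,
  "[M+H]+"          = 1.007276,
  "[M+NH4]+"        = 18.033823
)

ADDUCT_POLARITY <- c(
  "[M-H]-" = "negative", "[M+CH3COOH-H]-" = "negative",
  "[M+HCO2H-H]-" = "negative",
  "[M+H]+" = "positive", "[M+NH4]+" = "positive"
)

#' Construct an elemental formula
#'
#' Counts of C, H, N, O and P for a neutral molecule. Only these five
#' elements occur in the supported lipid classes.
#'
#' @param C,H,N,O,P Nonnegative integer element counts; at least one carbon.
#' @return An object of class `elemental_formula` (named integer vector).
#' @examples
#' elemental_formula(C = 18, H = 32, O = 2)  # linoleic acid
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  counts <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be nonnegative integers")
  if (counts["C"] < 1) stop("formula must contain at least one carbon")
  structure(as.integer(counts), names = names(counts),
            class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  parts <- vapply(names(x), function(el) {
    n <- x[[el]]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format(x), "(monoisotopic", sprintf("%.5f", monoisotopic_mass(x)), "Da)\n")
  invisible(x)
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula An [elemental_formula()].
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(inherits(formula, "elemental_formula"))
  sum(unclass(formula) * MONOISOTOPIC_MASS[names(formula)])
}

formula_add <- function(f, C = 0, H = 0, N = 0, O = 0, P = 0) {
  elemental_formula(C = f[["C"]] + C, H = f[["H"]] + H, N = f[["N"]] + N,
                    O = f[["O"]] + O, P = f[["P"]] + P)
}

# per-class diacyl/backbone composition as a function of total carbons c and
# total double bonds d (chain totals only; class backbone included)
LIPID_CLASS_RULES <- list(
  # fatty acid CcH(2c-2d)O2
  FA  = function(c, d) elemental_formula(C = c, H = 2 * c - 2 * d, O = 2),
  # glycerophosphocholine C8H20NO6P + n acyl residues
  PC  = function(c, d) elemental_formula(C = c + 8, H = 2 * c - 2 * d + 16,
                                         N = 1, O = 8, P = 1),
  LPC = function(c, d) elemental_formula(C = c + 8, H = 2 * c - 2 * d + 18,
                                         N = 1, O = 7, P = 1),
  # glycerophosphoethanolamine C5H14NO6P
  PE  = function(c, d) elemental_formula(C = c + 5, H = 2 * c - 2 * d + 10,
                                         N = 1, O = 8, P = 1),
  LPE = function(c, d) elemental_formula(C = c + 5, H = 2 * c - 2 * d + 12,
                                         N = 1, O = 7, P = 1),
  # glycerophosphoinositol C9H19O11P
  PI  = function(c, d) elemental_formula(C = c + 9, H = 2 * c - 2 * d + 15,
                                         O = 13, P = 1),
  # glycerol C3H8O3 + 3 acyls
  TG  = function(c, d) elemental_formula(C = c + 3, H = 2 * c - 2 * d + 2,
                                         O = 6),
  DG  = function(c, d) elemental_formula(C = c + 3, H = 2 * c - 2 * d + 4,
                                         O = 5),
  # sphingoid d-backbone (2 O, 1 N) + amide-linked acyl
  Cer = function(c, d) elemental_formula(C = c, H = 2 * c - 2 * d + 1,
                                         N = 1, O = 3),
  # Cer + hexose (C6H10O5)
  HexCer = function(c, d) elemental_formula(C = c + 6, H = 2 * c - 2 * d + 11,
                                            N = 1, O = 8),
  # Cer + phosphocholine (C5H12NO3P)
  SM  = function(c, d) elemental_formula(C = c + 5, H = 2 * c - 2 * d + 13,
                                         N = 2, O = 6, P = 1)
)

SPHINGOID_CLASSES <- c("Cer", "HexCer", "SM")
ETHER_CLASSES <- c("PC", "PE")  # classes for which an O- prefix is accepted

#' Parse a lipid shorthand name into an elemental formula
#'
#' Supports the `CLASS(total_C:total_DB)` shorthand with an optional `d`
#' sphingoid prefix, an optional `O-` ether prefix (glycerophospholipids
#' only), and chain-resolved descriptors with `_` or `/` separated chains
#' whose carbons and double bonds are summed. Supported classes: FA, LPC,
#' LPE, PC, PE, PI, TG, DG, Cer, HexCer, SM (plus the ether forms PC(O-...),
#' PE(O-...)).
#'
#' Hydroxylated sphingolipid descriptors (`-OH` suffix, `t` backbone) are
#' outside the grammar and raise an unsupported-name error rather than a
#' guessed composition.
#'
#' @param name Shorthand string, e.g. `"Cer(d34:1)"`, `"PC(16:0_16:0)"`,
#'   `"PC(O-32:0)"`, `"TG(18:0_18:1_18:2)"`.
#' @return An [elemental_formula()].
#' @examples
#' parse_lipid_shorthand("Cer(d34:1)")     # C34H67NO3
#' parse_lipid_shorthand("PC(16:0_16:0)")  # C40H80NO8P
#' @export
parse_lipid_shorthand <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  m <- regmatches(name, regexec("^([A-Za-z]+)\\((.+)\\)$", name))[[1]]
  if (length(m) != 3L)
    stop("malformed lipid shorthand: ", sQuote(name))
  class_tok <- m[2]
  desc <- m[3]

  if (!class_tok %in% names(LIPID_CLASS_RULES))
    stop("unknown lipid class token ", sQuote(class_tok), " in ", sQuote(name))
  if (grepl("-OH|\\bt\\d", desc))
    stop("unsupported hydroxylated/t-type sphingolipid descriptor in ",
         sQuote(name), "; composition is not guessed")

  ether <- FALSE
  if (startsWith(desc, "O-")) {
    if (!class_tok %in% ETHER_CLASSES)
      stop("ether (O-) prefix not supported for class ", sQuote(class_tok))
    ether <- TRUE
    desc <- substring(desc, 3)
  }

  sphingoid <- class_tok %in% SPHINGOID_CLASSES
  chains <- strsplit(desc, "[_/]")[[1]]
  total_c <- 0L
  total_d <- 0L
  for (i in seq_along(chains)) {
    ch <- chains[i]
    if (i == 1L && sphingoid) {
      if (!startsWith(ch, "d"))
        stop("sphingolipid descriptor must start with a 'd' backbone: ",
             sQuote(name))
      ch <- substring(ch, 2)
    } else if (startsWith(ch, "d")) {
      stop("unexpected 'd' prefix in chain ", sQuote(chains[i]),
           " of ", sQuote(name))
    }
    cm <- regmatches(ch, regexec("^([0-9]+):([0-9]+)$", ch))[[1]]
    if (length(cm) != 3L)
      stop("malformed chain descriptor ", sQuote(chains[i]),
           " in ", sQuote(name))
    total_c <- total_c + as.integer(cm[2])
    total_d <- total_d + as.integer(cm[3])
  }
  if (total_c <= 0L) stop("zero-carbon descriptor in ", sQuote(name))

  f <- LIPID_CLASS_RULES[[class_tok]](total_c, total_d)
  if (ether) f <- formula_add(f, H = 2, O = -1)
  f
}

#' Theoretical adduct m/z
#'
#' Monoisotopic neutral mass plus the adduct's mass delta under the
#' proton-transfer convention (1.007276 Da per charge; NH4 adds 18.033823 Da;
#' acetate adds 59.013853 Da; formate adds 44.998204 Da). All supported
#' adducts are singly charged.
#'
#' @param formula An [elemental_formula()], or a shorthand string passed to
#'   [parse_lipid_shorthand()].
#' @param adduct One of `"[M-H]-"`, `"[M+CH3COOH-H]-"`, `"[M+HCO2H-H]-"`,
#'   `"[M+H]+"`, `"[M+NH4]+"`. Unicode minus/plus decorations are normalized.
#' @return Theoretical m/z in Th.
#' @examples
#' adduct_mz(parse_lipid_shorthand("Cer(d34:1)"), "[M-H]-")  # 536.50482
#' @export
adduct_mz <- function(formula, adduct) {
  if (is.character(formula)) formula <- parse_lipid_shorthand(formula)
  adduct <- normalize_adduct(adduct)
  if (!adduct %in% names(ADDUCT_DELTAS))
    stop("unsupported adduct: ", sQuote(adduct))
  monoisotopic_mass(formula) + ADDUCT_DELTAS[[adduct]]
}

# fold unicode minus signs, spaces, super/subscript decorations and the
# formate spelling variant into the canonical ASCII adduct keys
normalize_adduct <- function(adduct) {
  a <- gsub("−|–", "-", adduct)
  a <- gsub("[[:space:]]", "", a)
  a <- gsub("\\^|_", "", a)
  a <- sub("H2CO2", "HCO2H", a, fixed = TRUE)
  a <- sub("HCOOH", "HCO2H", a, fixed = TRUE)
  a
}

adduct_polarity <- function(adduct) {
  a <- normalize_adduct(adduct)
  if (!a %in% names(ADDUCT_POLARITY)) stop("unsupported adduct: ", sQuote(adduct))
  ADDUCT_POLARITY[[a]]
}

#' Signed ppm mass error
#'
#' `1e6 * (experimental - theoretical) / theoretical`; the sign is preserved
#' (negative when the experimental m/z is below the theoretical one).
#'
#' @param mz_theoretical,mz_experimental m/z values in Th, both positive.
#' @return Signed error in ppm.
#' @examples
#' ppm_error(adduct_mz("Cer(d34:1)", "[M+CH3COOH-H]-"), 596.5285)  # ~4.28
#' @export
ppm_error <- function(mz_theoretical, mz_experimental) {
  if (any(mz_theoretical <= 0) || any(mz_experimental <= 0))
    stop("m/z values must be positive")
  1e6 * (mz_experimental - mz_theoretical) / mz_theoretical
}
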