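# Bound coherent neutron scattering lengths, in fm.
# Source: V.F. Sears, Neutron News 3(3), 26-37 (1992), Table 1.
# Deuterium has its own symbol "D" so that formulas can mix H and D
# explicitly; "H" always means 1H here.
.neutron_b_coh <- c(
  H = -3.7390, D = 6.6710, C = 6.6460, N = 9.3600, O = 5.8030,
  S = 2.8470, P = 5.1300, Na = 3.6300, Mg = 5.3750, Cl = 9.5770,
  K = 3.6700, Ca = 4.7000, Fe = 9.4500, Cu = 7.7180, Zn = 5.6800
)

# Standard atomic masses, g/mol (IUPAC 2021 abridged); D = 2H.
.atomic_mass <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, Na = 22.990, Mg = 24.305, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38
)

.N_AVOGADRO <- 6.02214076e23

# Reference waters for the solvent SLD line (densities at ~22 C, g/mL).
.WATER_H <- list(counts = c(H = 2, O = 1), density = 0.997)
.WATER_D <- list(counts = c(D = 2, O = 1), density = 1.105)

#' Parse an elemental formula string
#'
#' Converts a Hill-style elemental formula such as `"C8H13NO5"` into a named
#' count vector. Only elements with tabulated neutron scattering lengths are
#' accepted; write deuterium explicitly as `"D"`.
#'
#' @param formula Single character string, e.g. `"C8H13NO5"` or `"C6H7D3O5"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C8H13NO5")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("'formula' must be a single character string", call. = FALSE)
  }
  s <- gsub("[[:space:]]", "", formula)
  if (!nzchar(s)) stop("empty formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE))[[1]]
  if (sum(nchar(pieces)) != nchar(s)) {
    stop("could not parse formula: '", formula, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", pieces)
  num <- sub("^[A-Za-z]+", "", pieces)
  cnt <- ifelse(nzchar(num), as.integer(num), 1L)
  unknown <- setdiff(sym, names(.neutron_b_coh))
  if (length(unknown)) {
    stop("no tabulated scattering length for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# Accept a fraction given either on 0-1 scale or as "47%".
as_fraction <- function(x, what = "fraction") {
  if (is.character(x)) {
    if (!grepl("%$", trimws(x))) {
      stop(what, " given as character must carry an explicit '%' tag",
           call. = FALSE)
    }
    x <- as.numeric(sub("%$", "", trimws(x))) / 100
  }
  if (!is.numeric(x) || anyNA(x)) stop("invalid ", what, call. = FALSE)
  x
}
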