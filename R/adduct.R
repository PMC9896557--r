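#' @include AllClasses.R
NULL

## nominal (most-abundant-isotope) and monoisotopic masses for the elements
## needed in metal-carboxylate ESI-MS assignment work
.ELEMENTS <- local({
    tab <- rbind(
        H  = c(1,   1.0078250319),
        B  = c(11,  11.0093054),
        C  = c(12,  12.0),
        N  = c(14,  14.0030740052),
        O  = c(16,  15.9949146221),
        F  = c(19,  18.9984032),
        Na = c(23,  22.98976928),
        Mg = c(24,  23.985041697),
        Si = c(28,  27.9769265327),
        P  = c(31,  30.97376151),
        S  = c(32,  31.97207069),
        Cl = c(35,  34.96885271),
        K  = c(39,  38.9637064864),
        Ca = c(40,  39.962590863),
        Ti = c(48,  47.94794198),
        Cr = c(52,  51.94050623),
        Mn = c(55,  54.93804391),
        Fe = c(56,  55.93493633),
        Co = c(59,  58.93319429),
        Ni = c(58,  57.93534241),
        Cu = c(63,  62.92959772),
        Zn = c(64,  63.92914201),
        Se = c(80,  79.9165218),
        Br = c(79,  78.9183376),
        Mo = c(98,  97.90540482),
        Ru = c(102, 101.9043441),
        Rh = c(103, 102.905498),
        I  = c(127, 126.9044719),
        Pt = c(195, 194.9647917))
    colnames(tab) <- c("nominal", "monoisotopic")
    tab
})

## recursive-descent parser for elemental formulas with parentheses,
## e.g. "Co(C4H6O3)2(C2H3O2)" -> named count vector
.parseFormula <- function(formula) {
    chars <- strsplit(formula, "")[[1L]]
    pos <- 1L
    readCount <- function() {
        digits <- ""
        while (pos <= length(chars) && grepl("[0-9]", chars[pos])) {
            digits <- paste0(digits, chars[pos])
            pos <<- pos + 1L
        }
        if (nzchar(digits)) as.integer(digits) else 1L
    }
    parseGroup <- function() {
        counts <- integer()
        while (pos <= length(chars)) {
            ch <- chars[pos]
            if (ch == "(") {
                pos <<- pos + 1L
                inner <- parseGroup()
                if (pos > length(chars) || chars[pos] != ")")
                    stop("unbalanced parentheses in formula '", formula, "'")
                pos <<- pos + 1L
                mult <- readCount()
                for (el in names(inner))
                    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) +
                        inner[el] * mult
            } else if (ch == ")") {
                break
            } else if (grepl("[A-Z]", ch)) {
                el <- ch; pos <<- pos + 1L
                if (pos <= length(chars) && grepl("[a-z]", chars[pos])) {
                    el <- paste0(el, chars[pos]); pos <<- pos + 1L
                }
                n <- readCount()
                counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + n
            } else {
                stop("unexpected character '", ch, "' in formula '", formula, "'")
            }
        }
        counts
    }
    out <- parseGroup()
    if (pos <= length(chars))
        stop("unbalanced parentheses in formula '", formula, "'")
    if (!length(out)) stop("empty formula")
    out
}

#' Mass of an elemental formula
#'
#' @param formula elemental formula string, parentheses allowed
#'   (e.g. `"Co(C4H6O3)2(C2H3O2)"`).
#' @param monoisotopic use monoisotopic instead of nominal masses.
#' @return the formula mass (Da).
#' @export
formulaMass <- function(formula, monoisotopic = FALSE) {
    counts <- .parseFormula(formula)
    unknown <- setdiff(names(counts), rownames(.ELEMENTS))
    if (length(unknown))
        stop("unknown element(s): ", paste(unknown, collapse = ", "))
    col <- if (monoisotopic) "monoisotopic" else "nominal"
    sum(.ELEMENTS[names(counts), col] * counts)
}

#' m/z of an ionic core plus adducts
#'
#' Computes the mass-to-charge ratio of a charged core species after
#' attaching/removing neutral adducts and transferring electrons, as used
#' to check ESI-MS peak assignments such as a methanol adduct of a
#' dication after one-electron reduction. Each electron gained reduces the
#' charge by one; electrons are treated as massless at nominal resolution
#' (and also at monoisotopic resolution here, where sub-mDa accuracy is
#' not the goal).
#'
#' @param coreFormula elemental formula of the charged core.
#' @param coreCharge its integer charge (sign included).
#' @param adducts character vector of adduct formulas, each optionally
#'   prefixed by `"+"` (attach, default) or `"-"` (loss), e.g.
#'   `c("+CH4O", "-H2O")`.
#' @param electronTransfers net electrons gained (positive) or removed
#'   (negative).
#' @param monoisotopic use monoisotopic masses.
#' @return the m/z value: total mass / |resulting charge|.
#' @examples
#' ## methanol adduct of a 2+ core observed after one-electron reduction
#' adductMz("Co(C4H6O3)2(C2H3O2)", 2, "+CH4O", electronTransfers = 1)
#' @export
adductMz <- function(coreFormula, coreCharge, adducts = character(),
                     electronTransfers = 0L, monoisotopic = FALSE) {
    mass <- formulaMass(coreFormula, monoisotopic)
    for (a in adducts) {
        a <- trimws(a)
        sign <- 1
        if (startsWith(a, "-")) { sign <- -1; a <- substring(a, 2L) }
        else if (startsWith(a, "+")) a <- substring(a, 2L)
        mass <- mass + sign * formulaMass(a, monoisotopic)
    }
    charge <- coreCharge - electronTransfers
    if (charge == 0)
        stop("resulting charge is zero; m/z undefined")
    mass / abs(charge)
}
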