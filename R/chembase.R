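# Chemical ground truth: element masses, molecular formulas, and the
# residue / terminus / modification database every calculator consumes.

# package-local mutable state (databases loaded from extdata at load time)
the <- new.env(parent = emptyenv())

pepkit_datafile <- function(name) {
  path <- system.file("extdata", name, package = "pepkit")
  if (!nzchar(path)) stop("data file not found: ", name, call. = FALSE)
  path
}

read_table_file <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = NULL, check.names = FALSE)
}

# ---- molecular formulas ------------------------------------------------------

#' Create a molecular formula
#'
#' A `chem_formula` is a named integer vector mapping element symbols to
#' non-negative counts.  It is the universal currency for residues, termini
#' and adducts: formulas add and subtract element-wise, and subtraction that
#' would drive any count negative is an error.
#'
#' @param ... named integer counts, e.g. `chem_formula(C = 2, H = 3, N = 1, O = 1)`.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula(H = 2, O = 1) + chem_formula(C = 1)
#' @export
chem_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) {
    return(structure(integer(0), class = "chem_formula"))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("all formula counts must be named by element symbol", call. = FALSE)
  }
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("formula counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  names(counts) <- names(c(...))
  counts <- tapply(counts, names(counts), sum)  # merge duplicate symbols
  counts <- counts[counts > 0L]
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out[order(names(out))], class = "chem_formula")
}

as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_formula(x))
  stop("cannot interpret object as a molecular formula", call. = FALSE)
}

#' Parse a molecular formula string
#'
#' Accepts the usual compact notation, `(ElementSymbol Count?)+`, e.g.
#' `"C5H9NO"`.  Omitted counts default to 1; zero or negative counts and
#' unknown tokens are rejected with the offending position.
#'
#' @param text a single formula string.
#' @return A [chem_formula()].
#' @examples
#' parse_formula("C5H9NO")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  pos <- 1L
  n <- nchar(text)
  syms <- character(0)
  cnts <- integer(0)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0 || !nzchar(m[2])) {
      stop(sprintf("formula parse error at position %d of '%s': unrecognized token",
                   pos, text), call. = FALSE)
    }
    count <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (count < 1L) {
      stop(sprintf("formula parse error at position %d of '%s': count must be >= 1",
                   pos + nchar(m[2]), text), call. = FALSE)
    }
    syms <- c(syms, m[2])
    cnts <- c(cnts, count)
    pos <- pos + nchar(m[1])
  }
  do.call(chem_formula, as.list(stats::setNames(cnts, syms)))
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  e1 <- as_chem_formula(e1); e2 <- as_chem_formula(e2)
  all_sym <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(all_sym)), all_sym)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  do.call(chem_formula, as.list(out))
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is undefined for formulas", call. = FALSE)
  e1 <- as_chem_formula(e1); e2 <- as_chem_formula(e2)
  all_sym <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(all_sym)), all_sym)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] - unclass(e2)
  if (any(out < 0L)) {
    bad <- names(out)[out < 0L]
    stop("formula subtraction would give a negative count for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(chem_formula, as.list(out))
}

formula_scale <- function(f, k) {
  f <- as_chem_formula(f)
  stopifnot(k == round(k), k >= 0)
  do.call(chem_formula, as.list(unclass(f) * as.integer(k)))
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0) return("")
  syms <- names(x)
  # Hill order: C first, then H, then alphabetical; no C -> all alphabetical
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  counts <- unclass(x)[ord]
  paste0(ord, ifelse(counts > 1L, counts, ""), collapse = "")
}

#' @export
as.character.chem_formula <- function(x, ...) format(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  e1 <- as_chem_formula(e1); e2 <- as_chem_formula(e2)
  identical(unclass(e1)[order(names(e1))], unclass(e2)[order(names(e2))])
}

# ---- element masses and formula mass -----------------------------------------

#' Element mass table
#'
#' Masses of the single most abundant isotope of each supported element, in u.
#' Loaded from the versioned `elements.tsv` data file.
#'
#' @return Named numeric vector, element symbol to mass.
#' @export
element_masses <- function() the$elements

#' Monoisotopic mass of a formula
#'
#' Sums count times most-abundant-isotope element mass over the formula.
#'
#' @param f a [chem_formula()] or formula string.
#' @param masses element mass table; defaults to the shipped table.
#' @return Mass in u (0 for the empty formula).
#' @examples
#' formula_mass("H2O")  # 18.0106
#' @export
formula_mass <- function(f, masses = element_masses()) {
  f <- as_chem_formula(f)
  if (length(f) == 0) return(0)
  unknown <- setdiff(names(f), names(masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(unclass(f) * masses[names(f)])
}

# ---- database loading --------------------------------------------------------

load_default_database <- function() {
  the$elements <- local({
    tab <- read_table_file(pepkit_datafile("elements.tsv"))
    stats::setNames(tab$mass, tab$symbol)
  })

  res <- list(peptide = new.env(parent = emptyenv()),
              peptoid = new.env(parent = emptyenv()))
  pep <- read_table_file(pepkit_datafile("residues_peptide.tsv"))
  for (i in seq_len(nrow(pep))) {
    r <- pep[i, ]
    assign(r$code, list(
      code = r$code, polymer_class = "peptide", name = r$name,
      formula = parse_formula(r$formula), canonical = isTRUE(r$canonical),
      ionizable = if (r$ionizable == "-") NULL else r$ionizable,
      chromophore = if (r$chromophore == "-") NULL else r$chromophore
    ), envir = res$peptide)
  }
  ptd <- read_table_file(pepkit_datafile("residues_peptoid.tsv"))
  for (i in seq_len(nrow(ptd))) {
    r <- ptd[i, ]
    assign(r$code, list(
      code = r$code, polymer_class = "peptoid", name = r$name,
      formula = parse_formula(r$formula), canonical = FALSE,
      ionizable = NULL, chromophore = NULL
    ), envir = res$peptoid)
  }
  the$residues <- res

  trm <- read_table_file(pepkit_datafile("termini.tsv"))
  the$termini <- lapply(seq_len(nrow(trm)), function(i) {
    r <- trm[i, ]
    list(name = r$name, end = r$end, delta = parse_formula(r$delta),
         predefined = isTRUE(r$predefined))
  })
  names(the$termini) <- paste(trm$end, trm$name, sep = ":")

  mod <- read_table_file(pepkit_datafile("modifications.tsv"))
  the$modifications <- lapply(seq_len(nrow(mod)), function(i) {
    r <- mod[i, ]
    list(name = r$name, kind = r$kind,
         plus = parse_formula(r$plus), minus = parse_formula(r$minus),
         sites = if (r$sites == "-") character(0)
                 else strsplit(r$sites, ",", fixed = TRUE)[[1]],
         max_per_site = r$max_per_site)
  })
  names(the$modifications) <- mod$name

  pka <- read_table_file(pepkit_datafile("pka.tsv"))
  the$pka_default <- data.frame(group = pka$group, pka = pka$pka,
                                sign = pka$sign, stringsAsFactors = FALSE)

  cf <- read_table_file(pepkit_datafile("chou_fasman.tsv"))
  the$chou_fasman_default <- cf

  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  load_default_database()
}

#' Reset the residue / terminus / modification database
#'
#' Discards any residues or termini registered at run time and reloads the
#' shipped data files.
#' @return Invisibly `NULL`.
#' @export
reset_database <- function() load_default_database()

# ---- lookups and registration ------------------------------------------------

#' Look up a residue definition
#'
#' @param code residue code (case-sensitive).
#' @param polymer_class `"peptide"` or `"peptoid"`.
#' @return The residue record (list with `code`, `formula`, `canonical`, ...).
#' @export
lookup_residue <- function(code, polymer_class = c("peptide", "peptoid")) {
  polymer_class <- match.arg(polymer_class)
  env <- the$residues[[polymer_class]]
  if (!exists(code, envir = env, inherits = FALSE)) {
    known <- ls(env)
    near <- known[utils::adist(code, known) <= 1L]
    hint <- if (length(near)) paste0("; nearest matches: ",
                                     paste(sort(near), collapse = ", ")) else ""
    stop(sprintf("unknown %s residue code '%s'%s", polymer_class, code, hint),
         call. = FALSE)
  }
  get(code, envir = env, inherits = FALSE)
}

residue_codes <- function(polymer_class) ls(the$residues[[polymer_class]])

#' Register a residue at run time
#'
#' Extends the residue database programmatically; the new code is immediately
#' usable by the parsers and every calculator.
#'
#' @param code new residue code; must not collide within its polymer class.
#' @param polymer_class `"peptide"` or `"peptoid"`.
#' @param formula chain-incorporated (dehydrated) composition, as a
#'   [chem_formula()] or formula string.  Must be non-empty.
#' @param name optional long name.
#' @param canonical must be `FALSE`: the canonical set is fixed.
#' @return Invisibly, the stored residue record.
#' @export
register_residue <- function(code, polymer_class = c("peptide", "peptoid"),
                             formula, name = code, canonical = FALSE) {
  polymer_class <- match.arg(polymer_class)
  stopifnot(is.character(code), length(code) == 1, nzchar(code))
  if (grepl("[][()[:space:]-]", code)) {
    stop("residue codes may not contain whitespace, dashes or brackets",
         call. = FALSE)
  }
  if (isTRUE(canonical)) {
    stop("the canonical amino-acid set is fixed; register with canonical = FALSE",
         call. = FALSE)
  }
  env <- the$residues[[polymer_class]]
  if (exists(code, envir = env, inherits = FALSE)) {
    stop(sprintf("residue code '%s' already present in the %s database",
                 code, polymer_class), call. = FALSE)
  }
  formula <- as_chem_formula(formula)
  if (length(formula) == 0) stop("residue formula must be non-empty", call. = FALSE)
  formula_mass(formula)  # validates element symbols
  rec <- list(code = code, polymer_class = polymer_class, name = name,
              formula = formula, canonical = FALSE,
              ionizable = NULL, chromophore = NULL)
  assign(code, rec, envir = env)
  invisible(rec)
}

#' Look up or construct a terminus
#'
#' Predefined termini are selected by name (e.g. `"unmodified"`, `"acid"`,
#' `"amide"`, `"ethyl 3-mercaptopropionate thioester"`); a custom terminus is
#' given as a formula string, interpreted as the composition *added* to the
#' bare chain end.
#'
#' @param spec terminus name, or a formula string for a custom terminus.
#' @param end `"N"` or `"C"`.
#' @return A terminus record (list with `name`, `end`, `delta`, `predefined`).
#' @export
resolve_terminus <- function(spec, end = c("N", "C")) {
  end <- match.arg(end)
  if (inherits(spec, "pepkit_terminus")) {
    if (spec$end != end) stop("terminus is for the wrong chain end", call. = FALSE)
    return(spec)
  }
  stopifnot(is.character(spec), length(spec) == 1)
  key <- paste(end, spec, sep = ":")
  if (!is.null(the$termini[[key]])) {
    return(structure(the$termini[[key]], class = "pepkit_terminus"))
  }
  # fall back: treat as a custom formula
  delta <- tryCatch(parse_formula(spec), error = function(e) {
    avail <- sub(paste0("^", end, ":"), "",
                 grep(paste0("^", end, ":"), names(the$termini), value = TRUE))
    stop(sprintf(paste0("'%s' is neither a predefined %s-terminus (%s) nor a ",
                        "parsable formula string"),
                 spec, end, paste(avail, collapse = ", ")), call. = FALSE)
  })
  structure(list(name = paste0("custom (", format(delta), ")"), end = end,
                 delta = delta, predefined = FALSE),
            class = "pepkit_terminus")
}

#' Modification table
#'
#' Metal adducts and protecting groups known to the assignment engine.  Each
#' entry carries a signed composition change (`plus` minus `minus` formulas)
#' and the residue codes (or `Nterm`) that license it.
#'
#' @param names optional subset of modification names.
#' @return Named list of modification records.
#' @export
modification_table <- function(names = NULL) {
  if (is.null(names)) return(the$modifications)
  missing <- setdiff(names, base::names(the$modifications))
  if (length(missing)) {
    stop("unknown modification(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  the$modifications[names]
}

modification_delta_mass <- function(mod, masses = element_masses()) {
  formula_mass(mod$plus, masses) - formula_mass(mod$minus, masses)
}
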