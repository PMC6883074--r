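#' Atom selection language
#'
#' Selections are built from keyword clauses combined with `and`, `or`,
#' `not` and parentheses. `and` binds tighter than `or`. Supported keywords:
#'
#' \describe{
#'   \item{`name`}{atom name(s), e.g. `name CA` or `name CA CB`}
#'   \item{`resname`}{residue name(s), e.g. `resname LEU`}
#'   \item{`resid`}{residue number(s) and ranges, e.g. `resid 554 555` or
#'     `resid 553-559`}
#'   \item{`chain`}{chain/segment id(s), e.g. `chain A`}
#'   \item{`element`}{element symbol(s), e.g. `element O`}
#'   \item{`index`}{0-based atom indices and ranges}
#'   \item{`all` / `none`}{every / no atom}
#'   \item{`protein` / `water`}{standard amino-acid residues / water
#'     residues (`SOL`, `HOH`, `WAT`, `TIP3`, `SPC`, `W`)}
#' }
#'
#' Example: `"chain A and resid 554 and name CA"`.
#'
#' @param topology a `vw_topology`
#' @param expression selection string
#' @param empty_ok if `FALSE` (default) an empty selection is an error;
#'   if `TRUE` it is returned with a warning.
#' @return object of class `vw_selection`: list with `indices` (ordered,
#'   1-based, duplicate-free) and `expression`.
#' @export
select_atoms <- function(topology, expression, empty_ok = FALSE) {
  stopifnot(inherits(topology, "vw_topology"))
  tokens <- tokenize_selection(expression)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  mask <- parse_or(state, topology)
  if (state$pos <= length(state$tokens)) {
    stop("selection syntax error near '", state$tokens[state$pos],
         "' in: ", expression)
  }
  idx <- which(mask)
  if (length(idx) == 0L) {
    if (empty_ok) {
      warning("selection '", expression, "' matched no atoms")
    } else {
      stop("selection '", expression, "' matched no atoms")
    }
  }
  structure(list(indices = idx, expression = expression),
            class = "vw_selection")
}

#' @export
print.vw_selection <- function(x, ...) {
  cat("<vw_selection> ", length(x$indices), " atoms: '", x$expression,
      "'\n", sep = "")
  invisible(x)
}

WATER_RESNAMES <- c("SOL", "HOH", "WAT", "TIP3", "SPC", "W")

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

SELECTION_KEYWORDS <- c("name", "resname", "resid", "chain", "element",
                        "index", "all", "none", "protein", "water")

tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L ||
      !nzchar(trimws(expression))) {
    stop("selection expression must be a nonempty string")
  }
  s <- gsub("\\(", " ( ", expression)
  s <- gsub("\\)", " ) ", s)
  tokens <- strsplit(trimws(s), "\\s+")[[1L]]
  if (length(tokens) == 0L) stop("empty selection expression")
  tokens
}

peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_
  else state$tokens[state$pos]
}

advance <- function(state) {
  tok <- peek(state)
  state$pos <- state$pos + 1L
  tok
}

parse_or <- function(state, topology) {
  mask <- parse_and(state, topology)
  while (identical(tolower(peek(state)), "or")) {
    advance(state)
    mask <- mask | parse_and(state, topology)
  }
  mask
}

parse_and <- function(state, topology) {
  mask <- parse_unary(state, topology)
  while (identical(tolower(peek(state)), "and")) {
    advance(state)
    mask <- mask & parse_unary(state, topology)
  }
  mask
}

parse_unary <- function(state, topology) {
  tok <- peek(state)
  if (is.na(tok)) stop("selection expression ended unexpectedly")
  if (tolower(tok) == "not") {
    advance(state)
    return(!parse_unary(state, topology))
  }
  if (tok == "(") {
    advance(state)
    mask <- parse_or(state, topology)
    if (!identical(peek(state), ")")) stop("unbalanced parenthesis in selection")
    advance(state)
    return(mask)
  }
  parse_clause(state, topology)
}

parse_clause <- function(state, topology) {
  key <- tolower(advance(state))
  atoms <- topology$atoms
  n <- nrow(atoms)
  if (key == "all") return(rep(TRUE, n))
  if (key == "none") return(rep(FALSE, n))
  if (key == "protein") return(toupper(atoms$resname) %in% AMINO_ACIDS)
  if (key == "water") return(toupper(atoms$resname) %in% WATER_RESNAMES)
  if (!key %in% SELECTION_KEYWORDS) {
    stop("unknown selection keyword '", key, "'")
  }
  vals <- character(0)
  stops <- c(SELECTION_KEYWORDS, "and", "or", "not", "(", ")")
  while (!is.na(peek(state)) && !(tolower(peek(state)) %in% stops)) {
    vals <- c(vals, advance(state))
  }
  if (length(vals) == 0L) stop("keyword '", key, "' expects at least one value")
  switch(key,
    name     = toupper(atoms$name) %in% toupper(vals),
    resname  = toupper(atoms$resname) %in% toupper(vals),
    chain    = atoms$chain %in% vals,
    element  = toupper(atoms$element) %in% toupper(vals),
    resid    = atoms$resid %in% expand_int_values(vals, "resid"),
    index    = atoms$index %in% expand_int_values(vals, "index")
  )
}

expand_int_values <- function(vals, what) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+-[0-9]+$", v)) {
      # range a-b; a leading minus sign is not meaningful for resid/index
      parts <- regmatches(v, regexec("^(-?[0-9]+)-([0-9]+)$", v))[[1L]]
      lo <- as.integer(parts[2L]); hi <- as.integer(parts[3L])
      if (lo > hi) stop("invalid ", what, " range '", v, "'")
      out <- c(out, lo:hi)
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop("'", v, "' is not a valid ", what, " value")
    }
  }
  out
}

#' Positions of a selection in one frame
#' @param frame a `vw_frame`
#' @param selection a `vw_selection` (or integer indices)
#' @return n x 3 matrix of coordinates (nm)
#' @export
selection_xyz <- function(frame, selection) {
  idx <- if (inherits(selection, "vw_selection")) selection$indices
         else as.integer(selection)
  frame$xyz[idx, , drop = FALSE]
}
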