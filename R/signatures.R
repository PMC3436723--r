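#' @title Canonical circular atom signatures
#' @description
#' An atom signature is a canonical string describing the rooted environment
#' of one heavy atom out to a fixed number of bonds (the height). Two atoms
#' get the same text exactly when their height-h environments are
#' graph-isomorphic, taking element, formal charge, implicit-hydrogen count,
#' aromaticity and bond orders into account; the text is invariant under any
#' reordering of the molecule's atoms.
#'
#' The string grammar is a depth-first spanning tree with ring closures:
#'
#' ```
#' node    := '[' label ']' closure* ( '(' child+ ')' )?
#' child   := bond node
#' closure := bond '%' integer          # appears at both closure endpoints
#' bond    := '-' | '=' | '#' | ':'
#' label   := element ( ',' charge )? ( ',a' )? ',h' hcount
#' ```
#'
#' e.g. the height-1 signature of the carbonyl carbon of acetamide is
#' `[C,h0](-[C,h3]-[N,h2]=[O,h0])`.
#' @name atom-signatures
NULL

# label for one atom: element, charge when nonzero, 'a' when aromatic,
# then the implicit-hydrogen count
.atom_labels <- function(m) {
  paste0(
    m$element,
    ifelse(m$charge != 0L, sprintf(",%+d", m$charge), ""),
    ifelse(m$aromatic, ",a", ""),
    ",h", m$hcount
  )
}

.bond_symbols <- function(m) {
  ifelse(m$bond_aromatic, ":", c("-", "=", "#")[m$bond_order])
}

#' Atom signature of one atom
#'
#' @param mol an [npl_mol()].
#' @param root atom index (1-based) of the signature's root.
#' @param height number of bond layers to include (default 2).
#' @return the canonical signature string.
#' @seealso [atom-signatures] for the string grammar,
#'   [decode_signature()] for the inverse.
#' @export
atom_signature <- function(mol, root, height = 2L) {
  n <- mol_n_atoms(mol)
  root <- as.integer(root)
  if (length(root) != 1L || is.na(root) || root < 1L || root > n)
    abort(sprintf("root must be an atom index in 1..%d", n),
          class = "npl_invalid_root")
  cpp_atom_signatures(.atom_labels(mol), mol$bond_a, mol$bond_b,
                      .bond_symbols(mol), as.integer(height), root)
}

#' Molecular signature: one atom signature per heavy atom
#'
#' @param mol an [npl_mol()].
#' @param height signature height (default 2).
#' @return a tibble with columns `uuid`, `root` (atom index) and
#'   `signature`; exactly one row per heavy atom.
#' @export
molecular_signature <- function(mol, height = 2L) {
  n <- mol_n_atoms(mol)
  if (n == 0L) abort("molecule has no atoms", class = "npl_empty_input")
  sigs <- cpp_atom_signatures(.atom_labels(mol), mol$bond_a, mol$bond_b,
                              .bond_symbols(mol), as.integer(height),
                              seq_len(n))
  tibble(uuid = mol$uuid, root = seq_len(n), signature = sigs)
}

#' Generate signatures for a batch of molecules
#'
#' Fragments that share a UUID (e.g. after a sugar bridge was removed in
#' curation) are pooled under that UUID, so the scorer treats them as one
#' molecule.
#'
#' @param mols a tibble with columns `uuid` and `mol`, e.g. the `kept` table
#'   of [curate()], or a list of [npl_mol()] objects.
#' @param height signature height (default 2).
#' @return a tibble with columns `uuid` and `signature`, one row per heavy
#'   atom, in input order.
#' @export
sign_batch <- function(mols, height = 2L) {
  recs <- .as_mol_list(mols)
  if (!length(recs)) return(tibble(uuid = character(), signature = character()))
  out <- purrr::map(recs, function(m) {
    s <- molecular_signature(m, height = height)
    s[c("uuid", "signature")]
  })
  dplyr::bind_rows(out)
}

#' Decode a signature string back into its environment graph
#'
#' The inverse of [atom_signature()]: parses the canonical string into a
#' molecule whose first atom is the signature root, with implicit hydrogens,
#' charges and aromatic flags restored from the atom labels. Re-encoding the
#' result at the same height reproduces the text exactly.
#'
#' @param text a signature string.
#' @return an [npl_mol()]; the root is atom 1.
#' @export
decode_signature <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  st$chars <- strsplit(text, "")[[1L]]
  st$element <- character()
  st$charge <- integer()
  st$aromatic <- logical()
  st$hcount <- integer()
  st$bond_a <- integer()
  st$bond_b <- integer()
  st$bond_sym <- character()
  st$open <- list()  # closure id -> c(atom, sym)

  fail <- function(msg) {
    abort(sprintf("malformed signature at position %d: %s", st$pos, msg),
          class = "npl_parse_error")
  }
  peek <- function() {
    if (st$pos > length(st$chars)) "" else st$chars[[st$pos]]
  }
  take <- function() {
    ch <- peek()
    st$pos <- st$pos + 1L
    ch
  }
  read_int <- function() {
    d <- character()
    while (peek() %in% as.character(0:9)) d <- c(d, take())
    if (!length(d)) fail("expected digits")
    as.integer(paste(d, collapse = ""))
  }
  read_label <- function() {
    if (take() != "[") fail("expected '['")
    buf <- character()
    while (!peek() %in% c("]", "")) buf <- c(buf, take())
    if (take() != "]") fail("unterminated label")
    fields <- strsplit(paste(buf, collapse = ""), ",", fixed = TRUE)[[1L]]
    if (!length(fields)) fail("empty atom label")
    el <- fields[1L]
    if (!grepl("^[A-Z][a-z]?$", el)) fail(sprintf("bad element '%s'", el))
    charge <- 0L
    aromatic <- FALSE
    hcount <- NA_integer_
    for (f in fields[-1L]) {
      if (grepl("^[+-][0-9]+$", f)) charge <- as.integer(f)
      else if (f == "a") aromatic <- TRUE
      else if (grepl("^h[0-9]+$", f)) hcount <- as.integer(sub("^h", "", f))
      else fail(sprintf("bad label field '%s'", f))
    }
    if (is.na(hcount)) fail("label missing hydrogen count")
    st$element <- c(st$element, el)
    st$charge <- c(st$charge, charge)
    st$aromatic <- c(st$aromatic, aromatic)
    st$hcount <- c(st$hcount, hcount)
    length(st$element)
  }
  bond_order <- c(`-` = 1L, `=` = 2L, `#` = 3L, `:` = 1L)
  add_bond <- function(a, b, sym) {
    st$bond_a <- c(st$bond_a, a)
    st$bond_b <- c(st$bond_b, b)
    st$bond_sym <- c(st$bond_sym, sym)
  }
  read_node <- function() {
    v <- read_label()
    while (peek() %in% c("-", "=", "#", ":") &&
           st$pos < length(st$chars) && st$chars[[st$pos + 1L]] == "%") {
      sym <- take()
      take()  # '%'
      id <- as.character(read_int())
      if (is.null(st$open[[id]])) {
        st$open[[id]] <- list(atom = v, sym = sym)
      } else {
        prev <- st$open[[id]]
        if (prev$sym != sym) fail("closure bond symbols disagree")
        add_bond(prev$atom, v, sym)
        st$open[[id]] <- NULL
      }
    }
    if (peek() == "(") {
      take()
      repeat {
        ch <- peek()
        if (!ch %in% c("-", "=", "#", ":")) fail("expected bond symbol")
        sym <- take()
        u <- read_node()
        add_bond(v, u, sym)
        if (peek() == ")") { take(); break }
        if (peek() == "") fail("unterminated children")
      }
    }
    v
  }

  root <- read_node()
  if (st$pos <= length(st$chars)) fail("trailing characters")
  if (length(st$open)) fail("unmatched ring closure")
  m <- npl_mol(st$element, st$charge,
               data.frame(a = st$bond_a, b = st$bond_b,
                          order = unname(bond_order[st$bond_sym])),
               perceive = FALSE)
  m$hcount <- st$hcount
  m$aromatic <- st$aromatic
  m$bond_aromatic <- st$bond_sym == ":"
  attr(m, "root") <- root
  m
}
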