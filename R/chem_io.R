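#' Read molecules from an SDF (V2000) or SMILES file
#'
#' Every record is tagged with a UUID on read; an SDF record that already
#' carries one in its `NPL_UUID` data field keeps it. Explicit hydrogens are
#' folded into implicit counts. Records that fail to parse are skipped with
#' a message and counted in the `skipped` attribute of the result; only a
#' file with zero parsable records is an error.
#'
#' @param path input file.
#' @param format `"sdf"`, `"smiles"`, or `"auto"` (by file extension).
#' @param uuid_seed optional integer; when given, UUIDs are derived
#'   deterministically from this seed and the record index instead of being
#'   random, for reproducible pipelines.
#' @return a tibble with columns `uuid`, `name`, `mol` (list of [npl_mol()])
#'   and `origin`, one row per parsed record, in file order. Attribute
#'   `skipped` holds the number of unparsable records.
#' @export
read_molecules <- function(path, format = c("auto", "sdf", "smiles"),
                           uuid_seed = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(sprintf("input file not found: %s", path), class = "npl_input_error")
  if (format == "auto") {
    format <- if (grepl("\\.(smi|smiles|ism)$", path, ignore.case = TRUE))
      "smiles" else "sdf"
  }
  parsed <- if (format == "sdf") .read_sdf(path) else .read_smiles(path)
  mols <- parsed$mols
  if (!length(mols)) {
    abort(sprintf("no parsable records in %s (%d skipped)", path,
                  parsed$skipped),
          class = "npl_empty_input")
  }
  uuids <- vapply(mols, function(m) m$uuid %||% NA_character_, character(1))
  need <- is.na(uuids)
  uuids[need] <- npl_uuid(sum(need), seed = uuid_seed,
                          index = which(need))
  out <- tibble(
    uuid = uuids,
    name = vapply(mols, function(m) m$name %||% NA_character_, character(1)),
    mol = purrr::map2(mols, uuids, function(m, u) { m$uuid <- u; m }),
    origin = vapply(mols, function(m) m$origin, character(1))
  )
  attr(out, "skipped") <- parsed$skipped
  out
}

#' Generate UUIDs
#'
#' RFC-4122 version-4 identifiers drawn from R's random stream. With a
#' `seed`, identifiers are a pure function of `seed` and `index`, so a
#' pipeline re-run reproduces them exactly.
#'
#' @param n number of identifiers.
#' @param seed optional integer for deterministic identifiers.
#' @param index record indices used with `seed` (default `1:n`).
#' @return character vector of UUID strings.
#' @export
npl_uuid <- function(n, seed = NULL, index = seq_len(n)) {
  if (n == 0L) return(character())
  draw <- function(k) {
    bytes <- matrix(sample.int(256L, 16L * k, replace = TRUE) - 1L, nrow = 16L)
    bytes[7L, ] <- bitwOr(bitwAnd(bytes[7L, ], 15L), 64L)   # version 4
    bytes[9L, ] <- bitwOr(bitwAnd(bytes[9L, ], 63L), 128L)  # variant 10xx
    hx <- matrix(sprintf("%02x", bytes), nrow = 16L)
    apply(hx, 2L, function(h) paste0(
      paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
      paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
      paste(h[11:16], collapse = "")
    ))
  }
  if (is.null(seed)) return(draw(n))
  vapply(index, function(i) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed((as.integer(seed) + 1000003L * (i %% 2048L)) %% .Machine$integer.max)
    draw(1L)
  }, character(1))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- SDF (V2000) ----------------------------------------------------------

# Old-style atom-block charge codes (field 6 of the atom line).
.sdf_charge_code <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

.read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split on record delimiter
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, head(ends, -1L) + 1L)
  if (!length(ends)) { starts <- 1L; ends <- length(lines) + 1L }
  mols <- list()
  skipped <- 0L
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:min(ends[k], length(lines))]
    block <- block[trimws(block) != "$$$$"]
    if (all(!nzchar(trimws(block)))) next
    rec <- tryCatch(.parse_sdf_record(block, sprintf("%s#%d", path, k)),
                    error = function(e) e)
    if (inherits(rec, "condition")) {
      if (inherits(rec, "npl_v3000"))
        abort(conditionMessage(rec), class = "npl_input_error")
      inform(sprintf("skipping SDF record %d of %s: %s",
                     k, path, conditionMessage(rec)))
      skipped <- skipped + 1L
    } else {
      mols[[length(mols) + 1L]] <- rec
    }
  }
  list(mols = mols, skipped = skipped)
}

.parse_sdf_record <- function(block, origin) {
  if (length(block) < 4L) abort("truncated record")
  counts <- block[4L]
  if (grepl("V3000", counts))
    abort("V3000 connection tables are not supported; supply V2000 SDF",
          class = "npl_v3000")
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L)
    abort("bad counts line")
  if (length(block) < 4L + natoms + nbonds) abort("truncated atom/bond block")
  atom_lines <- block[4L + seq_len(natoms)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  if (any(!nzchar(element))) abort("missing element symbol")
  code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  charge <- unname(.sdf_charge_code[as.character(code)])
  charge[is.na(charge)] <- 0L
  bond_lines <- block[4L + natoms + seq_len(nbonds)]
  a <- suppressWarnings(as.integer(substr(bond_lines, 1L, 3L)))
  b <- suppressWarnings(as.integer(substr(bond_lines, 4L, 6L)))
  ord <- suppressWarnings(as.integer(substr(bond_lines, 7L, 9L)))
  if (any(is.na(a)) || any(is.na(b)) || any(is.na(ord)))
    abort("bad bond line")
  if (any(!ord %in% c(1:3, 4L))) abort("unsupported bond order")
  arom_in <- ord == 4L
  ord[arom_in] <- 1L
  # properties block: M CHG supersedes atom-block charges
  rest <- block[-seq_len(4L + natoms + nbonds)]
  chg_lines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0L, natoms)
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(cl, 7L, nchar(cl))), "\\s+")[[1L]])
      nent <- f[1L]
      for (j in seq_len(nent)) {
        charge[f[2L * j]] <- f[2L * j + 1L]
      }
    }
  }
  # data items
  uuid <- NA_character_
  mend <- grep("^M  END", rest)
  data_lines <- if (length(mend)) rest[-seq_len(mend[1L])] else character()
  hdr <- grep("^>", data_lines)
  for (h in hdr) {
    fname <- sub(".*<([^>]+)>.*", "\\1", data_lines[h])
    if (identical(fname, "NPL_UUID") && h < length(data_lines))
      uuid <- trimws(data_lines[h + 1L])
  }
  name <- trimws(block[1L])
  m <- npl_mol(element, charge,
               data.frame(a = a, b = b, order = ord),
               uuid = if (nzchar(uuid %||% "") && !is.na(uuid)) uuid else NA_character_,
               name = if (nzchar(name)) name else NA_character_,
               origin = origin, perceive = FALSE)
  # fold explicit hydrogens into implicit counts, then perceive
  hs <- which(m$element == "H")
  if (length(hs)) m <- mol_delete_atoms(m, hs)
  if (is.null(m)) abort("record contains only hydrogens")
  mol_check_valence(m)
  mol_perceive(m)
}

.write_sdf_record <- function(m, fields = NULL) {
  n <- mol_n_atoms(m)
  out <- c(
    if (!is.na(m$name)) m$name else "",
    "  nplikeness",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, length(m$bond_a)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, m$element),
    if (length(m$bond_a))
      sprintf("%3d%3d%3d  0  0  0  0", m$bond_a, m$bond_b, m$bond_order)
  )
  chg <- which(m$charge != 0L)
  while (length(chg)) {
    take <- chg[seq_len(min(8L, length(chg)))]
    chg <- chg[-seq_len(min(8L, length(chg)))]
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(take)),
                         paste(sprintf("%4d%4d", take, m$charge[take]),
                               collapse = "")))
  }
  out <- c(out, "M  END")
  fields <- c(list(NPL_UUID = m$uuid), as.list(fields))
  for (fn in names(fields)) {
    val <- fields[[fn]]
    if (is.null(val) || is.na(val)) next
    out <- c(out, sprintf(">  <%s>", fn), as.character(val), "")
  }
  c(out, "$$$$")
}

#' Write molecules to an SDF (V2000) or SMILES file
#'
#' SDF records carry the molecule's UUID in an `NPL_UUID` data field, so a
#' later [read_molecules()] restores identity; the written graph is the same
#' up to atom reordering. SMILES output has one `SMILES<TAB>name` line per
#' record (the UUID is used when a record has no name).
#'
#' @param mols a tibble as returned by [read_molecules()] (columns `uuid`,
#'   `mol`, optionally `name`), or a list of [npl_mol()] objects.
#' @param path output file.
#' @param format `"sdf"` or `"smiles"`.
#' @param fields optional data frame (one row per record) of extra SDF data
#'   fields, e.g. a fragment score.
#' @return the number of records written, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("sdf", "smiles"),
                            fields = NULL) {
  format <- match.arg(format)
  recs <- .as_mol_list(mols)
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(sprintf("cannot write %s", path),
                                            class = "npl_output_error"))
  on.exit(close(con))
  if (format == "sdf") {
    lines <- unlist(purrr::imap(recs, function(m, i) {
      .write_sdf_record(m, if (!is.null(fields)) fields[i, , drop = FALSE])
    }))
    writeLines(lines %||% character(), con)
  } else {
    lines <- vapply(recs, function(m) {
      smi <- .mol_to_smiles(m)
      nm <- if (!is.na(m$name)) m$name else m$uuid
      paste0(smi, "\t", nm %||% "")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(length(recs))
}

.as_mol_list <- function(mols) {
  if (is.data.frame(mols)) {
    recs <- mols[["mol"]]
    if (!is.null(mols[["uuid"]]))
      recs <- purrr::map2(recs, mols[["uuid"]], function(m, u) { m$uuid <- u; m })
    if (!is.null(mols[["name"]]))
      recs <- purrr::map2(recs, mols[["name"]], function(m, nm) { m$name <- nm; m })
    recs
  } else if (inherits(mols, "npl_mol")) {
    list(mols)
  } else {
    as.list(mols)
  }
}

# ---- SMILES via OpenBabel (ChemmineOB) ------------------------------------

.read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  mols <- list()
  skipped <- 0L
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "[ \t]+")[[1L]]
    smi <- tok[1L]
    nm <- if (length(tok) > 1L) paste(tok[-1L], collapse = " ") else NA_character_
    m <- tryCatch(parse_smiles(smi), error = function(e) NULL)
    if (is.null(m)) {
      inform(sprintf("skipping SMILES line %d of %s: unparsable", k, path))
      skipped <- skipped + 1L
      next
    }
    m$name <- nm
    m$origin <- sprintf("%s#%d", path, k)
    mols[[length(mols) + 1L]] <- m
  }
  list(mols = mols, skipped = skipped)
}

#' Parse a single SMILES string
#'
#' Conversion to a kekulized connection table is delegated to OpenBabel
#' (ChemmineOB); aromaticity is then re-perceived with this package's own
#' model so training and query molecules are always described identically.
#'
#' @param smiles a SMILES string.
#' @return an [npl_mol()].
#' @export
parse_smiles <- function(smiles) {
  sdf <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smiles, "\n"))
  )
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 5L)
    abort(sprintf("unparsable SMILES: %s", smiles), class = "npl_parse_error")
  .parse_sdf_record(lines, origin = "smiles")
}

.mol_to_smiles <- function(m) {
  sdf <- paste(c(.write_sdf_record(m), ""), collapse = "\n")
  smi <- ChemmineOB::convertFormat("SDF", "SMI", source = sdf)
  trimws(strsplit(smi, "[\t\n]")[[1L]][1L])
}

# ---- signature and score files --------------------------------------------

#' Read or write signature files
#'
#' The on-disk dialect is one record per line, `uuid<TAB>signature`, with no
#' header. Malformed lines are skipped with a message; a non-empty file with
#' only malformed lines is an error. A write followed by a read is
#' byte-identical.
#'
#' @param path file path.
#' @return `read_signatures()`: a tibble with columns `uuid`, `signature`.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path))
    abort(sprintf("input file not found: %s", path), class = "npl_input_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(tibble(uuid = character(), signature = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!any(ok))
    abort(sprintf("no well-formed lines in %s", path), class = "npl_input_error")
  if (any(!ok))
    inform(sprintf("skipped %d malformed line(s) in %s", sum(!ok), path))
  good <- parts[ok]
  tibble(
    uuid = vapply(good, `[[`, character(1), 1L),
    signature = vapply(good, `[[`, character(1), 2L)
  )
}

#' @rdname read_signatures
#' @param sigs a tibble with columns `uuid` and `signature`.
#' @return `write_signatures()`: number of records written, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  stopifnot(all(c("uuid", "signature") %in% names(sigs)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(sprintf("cannot write %s", path),
                                            class = "npl_output_error"))
  on.exit(close(con))
  writeLines(paste(sigs$uuid, sigs$signature, sep = "\t"), con)
  invisible(nrow(sigs))
}

#' Read or write score files
#'
#' One record per line, `uuid<TAB>score`, scores printed to 6 decimal
#' places.
#'
#' @param path file path.
#' @return `read_scores()`: a tibble with columns `uuid`, `np_likeness`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path))
    abort(sprintf("input file not found: %s", path), class = "npl_input_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 2L
  good <- parts[ok]
  tibble(
    uuid = vapply(good, `[[`, character(1), 1L),
    np_likeness = as.numeric(vapply(good, `[[`, character(1), 2L))
  )
}

#' @rdname read_scores
#' @param scores a tibble with columns `uuid` and `np_likeness`.
#' @return `write_scores()`: number of records written, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(all(c("uuid", "np_likeness") %in% names(scores)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(sprintf("cannot write %s", path),
                                            class = "npl_output_error"))
  on.exit(close(con))
  writeLines(sprintf("%s\t%.6f", scores$uuid, scores$np_likeness), con)
  invisible(nrow(scores))
}
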