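#' Read labeled compound records
#'
#' Reads either a delimited table with header columns
#' `smiles,label[,id]` (CSV or TSV, sniffed from the first line) or a plain
#' SMILES file (`.smi`: `SMILES<whitespace>id` per line) combined with a
#' single `label` argument.
#'
#' @param path Input file.
#' @param label Class label applied to every record when `path` is a plain
#'   SMILES file; ignored for delimited tables.
#' @param source Free-text provenance tag stored on each record.
#' @return A data.frame of molecule records with columns
#'   `id`, `smiles`, `label`, `source`.
#' @export
read_compounds <- function(path, label = NULL, source = basename(path)) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else NULL
  has_header <- grepl("smiles", tolower(first))
  if (!is.null(delim) && has_header) {
    df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("smiles", "label") %in% names(df))) {
      stop("read_compounds: need 'smiles' and 'label' columns")
    }
    if (is.null(df$id)) df$id <- paste0("cmp", seq_len(nrow(df)))
  } else {
    if (is.null(label)) {
      stop("read_compounds: plain SMILES input requires a 'label' argument")
    }
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    df <- data.frame(
      smiles = vapply(parts, `[`, character(1), 1),
      label = label,
      id = vapply(seq_along(parts), function(i) {
        if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("cmp", i)
      }, character(1)),
      stringsAsFactors = FALSE)
  }
  molecule_records(df$smiles, df$label, ids = df$id, source = source)
}

#' Build molecule records
#'
#' @param smiles Character vector of SMILES.
#' @param labels Class label per compound; each must be one of
#'   `inhibitor`, `non_inhibitor`, `substrate`, `non_substrate`.
#' @param ids Optional identifiers (default `cmp1`, `cmp2`, ...).
#' @param source Provenance tag.
#' @return data.frame with columns `id, smiles, label, source`.
#' @export
molecule_records <- function(smiles, labels, ids = NULL, source = "user") {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), pgp_classes())
  if (length(bad)) {
    stop("molecule_records: unknown label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(pgp_classes(), collapse = "/"), ")")
  }
  if (length(labels) == 1L) labels <- rep(labels, length(smiles))
  stopifnot(length(labels) == length(smiles))
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  data.frame(id = as.character(ids), smiles = as.character(smiles),
             label = labels, source = source, stringsAsFactors = FALSE)
}

#' The four Pgp endpoint classes
#'
#' @return Character vector of the recognised class labels.
#' @export
pgp_classes <- function() {
  c("inhibitor", "non_inhibitor", "substrate", "non_substrate")
}

#' Curate a compound dataset
#'
#' Applies the curation rules in a fixed order: records whose SMILES do not
#' parse are removed first, then compounds heavier than `mw_limit`
#' (average-mass molecular weight including implicit hydrogens), then
#' duplicates (same canonical SMILES and label; the first occurrence in
#' input order is kept), and finally overlapping compounds — a canonical
#' SMILES appearing under two or more distinct labels is discarded under
#' every label. Multi-fragment (dot-disconnected) SMILES are kept verbatim
#' but flagged.
#'
#' @param records data.frame from [molecule_records()] or
#'   [read_compounds()].
#' @param mw_limit Molecular-weight ceiling in Da (default 1000).
#' @return An object of class `curated_dataset`: list with
#'   `records` (kept rows, with a `canonical` column), `removed`
#'   (rows with a `reason` column, one of `unparseable`, `overweight`,
#'   `duplicate`, `overlapping`), `census` (named per-label counts plus
#'   `total`) and `multi_fragment` (ids of dot-disconnected SMILES).
#' @export
curate <- function(records, mw_limit = 1000) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("id", "smiles", "label") %in% names(records)))
  bad <- setdiff(unique(records$label), pgp_classes())
  if (length(bad)) {
    stop("curate: unknown label(s): ", paste(bad, collapse = ", "))
  }
  rec <- records
  rec$canonical <- canonicalize_smiles(rec$smiles)
  removed <- rec[0, , drop = FALSE]
  removed$reason <- character(0)

  drop_rows <- function(keep_mask, reason) {
    if (any(!keep_mask)) {
      gone <- rec[!keep_mask, , drop = FALSE]
      gone$reason <- reason
      removed <<- rbind(removed, gone)
      rec <<- rec[keep_mask, , drop = FALSE]
    }
  }

  drop_rows(!is.na(rec$canonical), "unparseable")
  if (nrow(rec)) {
    mw <- molecular_weight(rec$canonical)
    drop_rows(!is.na(mw) & mw <= mw_limit, "overweight")
  }
  if (nrow(rec)) {
    drop_rows(!duplicated(paste(rec$canonical, rec$label, sep = "\r")),
              "duplicate")
  }
  if (nrow(rec)) {
    nlab <- tapply(rec$label, rec$canonical,
                   function(l) length(unique(l)))
    drop_rows(!(rec$canonical %in% names(nlab)[nlab > 1]), "overlapping")
  }

  rownames(rec) <- rownames(removed) <- NULL
  cen <- census_counts(rec$label)
  if (cen[["total"]] == 0) {
    warning("curate: all records removed; dataset is empty")
  }
  structure(list(records = rec, removed = removed, census = cen,
                 multi_fragment = rec$id[grepl(".", rec$canonical,
                                               fixed = TRUE)],
                 mw_limit = mw_limit),
            class = "curated_dataset")
}

census_counts <- function(labels) {
  counts <- vapply(pgp_classes(), function(cl) sum(labels == cl), integer(1))
  c(counts, total = sum(counts))
}

#' Per-class census of a curated dataset
#'
#' @param dataset A `curated_dataset` from [curate()], or a character vector
#'   of labels.
#' @return Named integer vector: one count per endpoint class plus `total`
#'   (which always equals the sum of the class counts).
#' @export
census <- function(dataset) {
  if (inherits(dataset, "curated_dataset")) return(dataset$census)
  census_counts(as.character(dataset))
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("curated_dataset:", nrow(x$records), "kept,",
      nrow(x$removed), "removed (MW limit", x$mw_limit, "Da)\n")
  print(x$census)
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' Write curation artifacts
#'
#' Emits the curated table (input schema plus the canonical SMILES), the
#' removal log and the census.
#'
#' @param dataset A `curated_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_curation <- function(dataset, dir) {
  stopifnot(inherits(dataset, "curated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(curated = file.path(dir, "curated.csv"),
             removed = file.path(dir, "removed.csv"),
             census = file.path(dir, "census.json"))
  utils::write.csv(dataset$records, paths["curated"], row.names = FALSE)
  utils::write.csv(dataset$removed[c("id", "smiles", "label", "reason")],
                   paths["removed"], row.names = FALSE)
  jsonlite::write_json(as.list(dataset$census), paths["census"],
                       auto_unbox = TRUE)
  invisible(paths)
}
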