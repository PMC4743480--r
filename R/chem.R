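#' Canonicalize a SMILES string
#'
#' Converts SMILES to the Open Babel canonical form so that different
#' notations of the same molecule map to one deterministic representation.
#' Canonicalization is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where the input does
#'   not parse (see [curate()] for how unparseable records are routed).
#' @examples
#' \donttest{
#' canonicalize_smiles(c("OCC", "CCO"))  # identical output
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), all(nzchar(smiles) | is.na(smiles)))
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) "")
    out <- sub("\\s+$", "", strsplit(out, "[\t\n]")[[1]][1])
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Parse one SMILES into an explicit-hydrogen structure.
# Returns NULL when the SMILES does not parse. The result carries:
#   elements  - element symbol per atom (explicit H included)
#   bonds     - data.frame(from, to, order) over all atoms
#   n_heavy   - heavy atom count
parse_structure <- function(smiles) {
  sdftxt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", smiles,
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))),
    error = function(e) "")
  if (!nzchar(sdftxt)) return(NULL)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(
      ChemmineR::read.SDFstr(textConnection(sdftxt)))),
    error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) < 1) return(NULL)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  elements <- sub("_.*$", "", rownames(ab))
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    bb <- as.matrix(bb)
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  list(elements = elements, bonds = bonds,
       n_heavy = sum(elements != "H"), smiles = smiles)
}

# Open Babel atomic-contribution properties (MW, logP, TPSA) for a vector
# of SMILES. Returns a data.frame with one row per input; NA rows where the
# SMILES fails to convert.
ob_properties <- function(smiles) {
  out <- data.frame(MW = rep(NA_real_, length(smiles)),
                    ALogP = NA_real_, TPSA = NA_real_)
  for (i in seq_along(smiles)) {
    sdftxt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "SDF", smiles[i],
        options = data.frame(names = "h", args = "",
                             stringsAsFactors = FALSE))),
      error = function(e) "")
    if (!nzchar(sdftxt)) next
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(
        ChemmineR::read.SDFstr(textConnection(sdftxt)))),
      error = function(e) NULL)
    if (is.null(sdfset) || length(sdfset) < 1) next
    p <- tryCatch(suppressWarnings(ChemmineR::propOB(sdfset[1])),
                  error = function(e) NULL)
    if (is.null(p)) next
    out$MW[i] <- as.numeric(p$MW[1])
    out$ALogP[i] <- as.numeric(p$logP[1])
    out$TPSA[i] <- as.numeric(p$TPSA[1])
  }
  out
}

# Average-mass molecular weight of one SMILES (explicit-H structure),
# NA if unparseable. Used by the curation MW filter.
molecular_weight <- function(smiles) {
  ob_properties(smiles)$MW
}
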