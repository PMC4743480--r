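#' Compute the seven interpretable 2D descriptors
#'
#' For each SMILES the following descriptors are computed from the parsed
#' explicit-hydrogen structure:
#' \describe{
#'   \item{MW}{average-atomic-mass molecular weight (Da), implicit
#'     hydrogens included.}
#'   \item{RBN}{rotatable bond number: single, acyclic bonds between two
#'     non-terminal heavy atoms, excluding amide C–N bonds.}
#'   \item{nCIC}{number of rings: the cyclomatic number of the heavy-atom
#'     graph (bonds − atoms + connected components).}
#'   \item{nHDon}{hydrogen-bond donors: hydrogen atoms bonded to N or O.}
#'   \item{nHAcc}{hydrogen-bond acceptors: count of N, O and F atoms.}
#'   \item{ALogP}{octanol–water partition coefficient by the
#'     Ghose–Crippen-type atomic-contribution scheme (Wildman–Crippen
#'     parameterisation, via Open Babel).}
#'   \item{TPSA}{topological polar surface area (Ertl fragment
#'     contributions), in squared Angstroms.}
#' }
#'
#' @param smiles Character vector of SMILES.
#' @return data.frame with columns `MW, RBN, nCIC, nHDon, nHAcc, ALogP,
#'   TPSA`, one row per input. Rows are `NA` where the SMILES does not
#'   parse; a structure with zero heavy atoms is an error.
#' @examples
#' \donttest{
#' compute_descriptors("CCO")  # ethanol: 1 donor, 1 acceptor, no rings
#' }
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  props <- ob_properties(smiles)
  graph <- t(vapply(smiles, function(s) {
    st <- parse_structure(s)
    if (is.null(st)) {
      return(c(RBN = NA_real_, nCIC = NA_real_,
               nHDon = NA_real_, nHAcc = NA_real_))
    }
    if (st$n_heavy == 0) {
      stop("compute_descriptors: structure with zero heavy atoms: ", s)
    }
    graph_descriptors(st)
  }, numeric(4)))
  out <- data.frame(MW = props$MW, RBN = graph[, "RBN"],
                    nCIC = graph[, "nCIC"], nHDon = graph[, "nHDon"],
                    nHAcc = graph[, "nHAcc"], ALogP = props$ALogP,
                    TPSA = props$TPSA)
  rownames(out) <- NULL
  out
}

#' Fixed descriptor column order
#' @return Character vector of the seven 2D descriptor names, then the six
#'   quantum-chemical names.
#' @export
descriptor_names <- function() {
  c("MW", "RBN", "nCIC", "nHDon", "nHAcc", "ALogP", "TPSA")
}

#' @rdname descriptor_names
#' @export
quantum_names <- function() {
  c("Qm", "energy", "dipole", "HOMO", "LUMO", "gap")
}

# RBN / nCIC / nHDon / nHAcc from an explicit-H structure (parse_structure)
graph_descriptors <- function(st) {
  el <- st$elements
  heavy <- el != "H"
  hidx <- which(heavy)
  b <- st$bonds
  nHAcc <- sum(el %in% c("N", "O", "F"))
  # donors: H atoms bonded to N or O
  endN_O <- function(i, j) el[i] == "H" & el[j] %in% c("N", "O")
  nHDon <- sum(endN_O(b$from, b$to) | endN_O(b$to, b$from))
  # heavy-atom graph
  hb <- b[el[b$from] != "H" & el[b$to] != "H", , drop = FALSE]
  ncomp_graph <- igraph::graph_from_data_frame(
    data.frame(from = match(hb$from, hidx), to = match(hb$to, hidx)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(hidx)))
  comp <- igraph::components(ncomp_graph)$no
  nCIC <- nrow(hb) - length(hidx) + comp
  # ring bonds = non-bridges of the heavy graph
  in_ring <- rep(TRUE, nrow(hb))
  in_ring[as.integer(igraph::bridges(ncomp_graph))] <- FALSE
  hdeg <- tabulate(c(hb$from, hb$to), nbins = length(el))
  # amide C-N: single C-N bond whose carbon carries a double bond to O
  carbonyl_c <- unique(c(
    b$from[el[b$from] == "C" & el[b$to] == "O" & b$order == 2],
    b$to[el[b$to] == "C" & el[b$from] == "O" & b$order == 2]))
  RBN <- 0L
  if (nrow(hb)) {
    idx <- hb$order == 1 & !in_ring & hdeg[hb$from] >= 2 & hdeg[hb$to] >= 2
    cand <- hb[idx, , drop = FALSE]
    amide <- (el[cand$from] == "C" & el[cand$to] == "N" &
                cand$from %in% carbonyl_c) |
             (el[cand$to] == "C" & el[cand$from] == "N" &
                cand$to %in% carbonyl_c)
    RBN <- sum(!amide)
  }
  c(RBN = RBN, nCIC = nCIC, nHDon = nHDon, nHAcc = nHAcc)
}

#' Build a feature table of descriptors from a curated dataset
#'
#' One row per curated record, columns in the fixed [descriptor_names()]
#' order. Records whose descriptors cannot be computed are dropped and
#' logged on the returned object (attribute `dropped`).
#'
#' @param dataset A `curated_dataset` from [curate()], or a data.frame with
#'   `id`, `smiles` (or `canonical`) and `label` columns.
#' @param positive Positive class for downstream modelling; defaults to the
#'   first label level.
#' @return A [feature_table()] (rows x 7 descriptors), with attribute
#'   `dropped`: data.frame of ids and reasons for any dropped records.
#' @export
build_feature_table <- function(dataset, positive = NULL) {
  if (inherits(dataset, "curated_dataset")) dataset <- dataset$records
  stopifnot(is.data.frame(dataset))
  if (nrow(dataset) == 0) stop("build_feature_table: empty input")
  smi <- if (!is.null(dataset$canonical)) dataset$canonical else dataset$smiles
  desc <- compute_descriptors(smi)
  ok <- stats::complete.cases(desc)
  dropped <- data.frame(id = dataset$id[!ok],
                        reason = rep("descriptor_failure", sum(!ok)),
                        stringsAsFactors = FALSE)
  ft <- feature_table(as.matrix(desc[ok, descriptor_names()]),
                      dataset$label[ok], ids = dataset$id[ok],
                      positive = positive)
  attr(ft, "dropped") <- dropped
  ft
}

#' Attach precomputed quantum-chemical descriptors
#'
#' The six quantum-chemical descriptors (mean absolute partial charge Qm,
#' total energy, dipole moment, HOMO, LUMO and the HOMO–LUMO gap) come
#' from an external electronic-structure calculation and are merged by id;
#' they are never computed internally.
#'
#' @param ft A [feature_table()].
#' @param quantum A CSV path or data.frame with columns
#'   `id,Qm,energy,dipole,HOMO,LUMO[,gap]`. If `gap` is absent it is
#'   computed as `LUMO - HOMO`; if present it must agree with
#'   `LUMO - HOMO` within `1e-3` eV.
#' @return The feature table with the six quantum columns appended.
#' @export
attach_quantum_block <- function(ft, quantum) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.character(quantum)) {
    quantum <- utils::read.csv(quantum, stringsAsFactors = FALSE)
  }
  need <- c("id", "Qm", "energy", "dipole", "HOMO", "LUMO")
  miss_col <- setdiff(need, names(quantum))
  if (length(miss_col)) {
    stop("attach_quantum_block: missing columns: ",
         paste(miss_col, collapse = ", "))
  }
  idx <- match(ft$ids, as.character(quantum$id))
  if (anyNA(idx)) {
    stop("attach_quantum_block: ids missing from quantum data: ",
         paste(ft$ids[is.na(idx)], collapse = ", "))
  }
  q <- quantum[idx, , drop = FALSE]
  gap_calc <- q$LUMO - q$HOMO
  if (is.null(q$gap)) {
    q$gap <- gap_calc
  } else if (any(abs(q$gap - gap_calc) > 1e-3)) {
    bad <- as.character(q$id[abs(q$gap - gap_calc) > 1e-3])
    stop("attach_quantum_block: gap inconsistent with LUMO - HOMO for: ",
         paste(bad, collapse = ", "))
  }
  if (any(q$Qm < 0) || any(q$dipole < 0)) {
    stop("attach_quantum_block: Qm and dipole must be nonnegative")
  }
  feature_table(cbind(ft$x, as.matrix(q[quantum_names()])),
                ft$labels, ids = ft$ids, positive = ft$positive)
}
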