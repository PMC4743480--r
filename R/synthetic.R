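#' Specification for a synthetic descriptor table
#'
#' Describes the statistical structure the pipeline assumes: two classes
#' with Gaussian class-conditional features, a tunable per-feature class
#' separation, planted collinear feature pairs to exercise the pruning
#' stage, and positive-class subpopulations of differing label quality to
#' exercise cluster selection. Feature scales mimic descriptor ranges
#' (the first columns are rounded to nonnegative integers, like atom and
#' bond counts) so the integer invariants of real descriptor vectors stay
#' exercisable.
#'
#' @param n_pos,n_neg Class sizes. Defaults 1341 and 913, the
#'   inhibitor-task census.
#' @param n_features Total feature count including planted collinear
#'   columns (default 11).
#' @param delta Class separation: difference between the class means of
#'   each base feature, in pooled-SD units (default 1.5).
#' @param collinear_pairs List of `c(source = <column index>, r = <target
#'   absolute correlation>)` pairs; each occupies one of the last columns,
#'   built as `y = r * x_std + sqrt(1 - r^2) * noise`. Target `|r|` must
#'   exceed 0.7.
#' @param pos_subpopulations List of `list(weight=, noise=)` describing
#'   positive-class subpopulations; `noise` is the fraction of that
#'   subpopulation drawn from the negative class distribution while
#'   labelled positive. Weights must sum to 1, noise rates lie in
#'   [0, 0.5]. Default: a single clean subpopulation.
#' @param seed Integer seed; every random draw flows from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 1341, n_neg = 913, n_features = 11,
                           delta = 1.5, collinear_pairs = list(),
                           pos_subpopulations = list(list(weight = 1,
                                                          noise = 0)),
                           seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, delta >= 0, n_features >= 1)
  if (length(collinear_pairs) >= n_features) {
    stop("synthetic_spec: more planted columns than features")
  }
  for (p in collinear_pairs) {
    if (p[["r"]] <= 0.7 || p[["r"]] > 1) {
      stop("synthetic_spec: planted |r| must lie in (0.7, 1]")
    }
  }
  w <- vapply(pos_subpopulations, `[[`, numeric(1), "weight")
  nz <- vapply(pos_subpopulations, `[[`, numeric(1), "noise")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("synthetic_spec: subpopulation weights must sum to 1")
  }
  if (any(nz < 0 | nz > 0.5)) {
    stop("synthetic_spec: noise rates must lie in [0, 0.5]")
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, n_features = n_features,
                 delta = delta, collinear_pairs = collinear_pairs,
                 pos_subpopulations = pos_subpopulations, seed = seed),
            class = "synthetic_spec")
}

# descriptor-like column scales: (location, scale, integer?)
column_scales <- function(n_features, n_planted) {
  base <- n_features - n_planted
  loc <- c(350, 5, 2, 2, 4, rep(0, max(0, base - 5)))[seq_len(base)]
  scl <- c(120, 3, 1.5, 1.5, 2, rep(1, max(0, base - 5)))[seq_len(base)]
  int <- seq_len(base) %in% 2:5
  list(location = loc, scale = scl, integer = int)
}

#' Generate a synthetic feature table
#'
#' Produces a class-labelled Gaussian feature table following a
#' [synthetic_spec()]: base features are class-conditional Gaussians whose
#' class means differ by `delta` pooled SDs, planted collinear columns are
#' exact linear blends `r * x_std + sqrt(1 - r^2) * noise` of their source
#' column, positive rows are drawn from the configured subpopulations, and
#' everything is reproducible from the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a [feature_table()], positive class
#'   `"pos"`), and `truth` (class `ground_truth`: per-feature class means
#'   in z-space, planted column names with sources and target r,
#'   subpopulation index per positive row, and which rows carry flipped
#'   labels).
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  n <- spec$n_pos + spec$n_neg
  n_planted <- length(spec$collinear_pairs)
  base <- spec$n_features - n_planted
  labels <- c(rep("pos", spec$n_pos), rep("neg", spec$n_neg))

  subpop <- assign_subpops(spec, rng)
  noisy <- subpop$noisy
  z <- matrix(rng$rnorm(n * base), n, base)
  # positive rows (except noise-flipped ones) get the +delta mean shift
  shifted <- c(!noisy, rep(FALSE, spec$n_neg))
  z[shifted, ] <- z[shifted, ] + spec$delta

  planted <- matrix(0, n, 0)
  planted_names <- character(0)
  truth_pairs <- list()
  for (i in seq_along(spec$collinear_pairs)) {
    p <- spec$collinear_pairs[[i]]
    src <- as.integer(p[["source"]]); r <- p[["r"]]
    stopifnot(src >= 1, src <= base)
    xs <- as.numeric(scale(z[, src]))
    col <- r * xs + sqrt(1 - r^2) * rng$rnorm(n)
    planted <- cbind(planted, col)
    nm <- paste0("f", base + i)
    planted_names <- c(planted_names, nm)
    truth_pairs[[i]] <- list(column = nm, source = paste0("f", src),
                             target_r = r)
  }

  sc <- column_scales(spec$n_features, n_planted)
  xobs <- sweep(sweep(z, 2, sc$scale, "*"), 2, sc$location, "+")
  xobs[, sc$integer] <- pmax(0, round(xobs[, sc$integer]))
  x <- cbind(xobs, planted)
  colnames(x) <- paste0("f", seq_len(spec$n_features))

  ft <- feature_table(x, labels, positive = "pos")
  truth <- structure(list(
    class_mean_shift = spec$delta,
    planted = truth_pairs,
    planted_columns = planted_names,
    subpopulation = subpop$index,
    noisy_rows = which(noisy),
    column_scales = sc), class = "ground_truth")
  list(table = ft, truth = truth)
}

assign_subpops <- function(spec, rng) {
  w <- vapply(spec$pos_subpopulations, `[[`, numeric(1), "weight")
  nz <- vapply(spec$pos_subpopulations, `[[`, numeric(1), "noise")
  counts <- floor(spec$n_pos * w)
  rem <- spec$n_pos - sum(counts)
  if (rem > 0) {
    frac <- spec$n_pos * w - counts
    ord <- order(frac, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  index <- rep(seq_along(w), counts)
  noisy <- logical(spec$n_pos)
  for (s in seq_along(w)) {
    members <- which(index == s)
    n_noise <- round(nz[s] * length(members))
    if (n_noise > 0) noisy[rng$sample(members, n_noise)] <- TRUE
  }
  list(index = index, noisy = noisy)
}

#' Generate an imbalanced two-table scenario for cluster selection
#'
#' Emulates the imbalance-correction setting: negatives sit at the origin
#' of feature space, positive subpopulation `s` is centred `s * delta`
#' pooled SDs away on every base feature (so subpopulations are
#' geometrically separated from the negatives and from each other), and a
#' subpopulation's label-noise rows are drawn from the negative
#' distribution while keeping the positive label. Exactly one
#' subpopulation must be noise-free; it is the recoverable ground truth
#' that FCM cluster selection should isolate.
#'
#' @param spec A [synthetic_spec()] with `n_pos > n_neg` and at least two
#'   subpopulations, exactly one of which has noise rate 0. Default
#'   subpopulations when the spec carries only the trivial single clean
#'   one: clean weight 0.45 (noise 0) and noisy weight 0.55 (noise 0.3),
#'   mirroring a selected-cluster fraction of roughly 0.45.
#' @return List with `positives`, `negatives` (both [feature_table()]s)
#'   and `truth` (`ground_truth` with `clean_rows`: positive-row indices
#'   of the noise-free subpopulation).
#' @export
generate_imbalanced_scenario <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$pos_subpopulations) < 2) {
    spec$pos_subpopulations <- list(list(weight = 0.45, noise = 0),
                                    list(weight = 0.55, noise = 0.3))
  }
  if (spec$n_pos <= spec$n_neg) {
    stop("generate_imbalanced_scenario: positives must outnumber negatives")
  }
  nz <- vapply(spec$pos_subpopulations, `[[`, numeric(1), "noise")
  if (sum(nz == 0) != 1) {
    stop("generate_imbalanced_scenario: exactly one subpopulation must be ",
         "noise-free (recoverable ground truth)")
  }
  rng <- local_rng(spec$seed)
  base <- spec$n_features - length(spec$collinear_pairs)
  subpop <- assign_subpops(spec, rng)
  # order subpopulations so the clean one is farthest from the negatives
  shift_rank <- order(nz == 0)            # clean last = largest shift
  shift <- match(seq_along(nz), shift_rank) * spec$delta
  zp <- matrix(rng$rnorm(spec$n_pos * base), spec$n_pos, base)
  zp <- zp + outer(ifelse(subpop$noisy, 0, shift[subpop$index]),
                   rep(1, base))
  zn <- matrix(rng$rnorm(spec$n_neg * base), spec$n_neg, base)
  sc <- column_scales(spec$n_features, 0)
  obs <- function(z) {
    x <- sweep(sweep(z, 2, sc$scale, "*"), 2, sc$location, "+")
    x[, sc$integer] <- pmax(0, round(x[, sc$integer]))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    x
  }
  positives <- feature_table(obs(zp), rep("pos", spec$n_pos),
                             ids = paste0("p", seq_len(spec$n_pos)),
                             positive = "pos")
  negatives <- feature_table(obs(zn), rep("neg", spec$n_neg),
                             ids = paste0("n", seq_len(spec$n_neg)))
  clean_pop <- which(nz == 0)
  truth <- structure(list(
    subpopulation = subpop$index,
    noisy_rows = which(subpop$noisy),
    clean_rows = which(subpop$index == clean_pop & !subpop$noisy),
    clean_subpopulation = clean_pop,
    shift_per_subpopulation = shift,
    column_scales = sc), class = "ground_truth")
  list(positives = positives, negatives = negatives, truth = truth)
}

#' Hand-verified toy molecule fixtures
#'
#' A small set of common molecules with expected values of the integer
#' descriptors, derived by hand from the package's stated conventions
#' (acceptors = N/O/F atoms; donors = H on N/O; rotatable bonds = single
#' acyclic bonds between non-terminal heavy atoms excluding amide C–N;
#' rings = cyclomatic number) and average-mass molecular weights.
#'
#' @return data.frame with columns `name, smiles, MW, RBN, nCIC, nHDon,
#'   nHAcc`.
#' @export
generate_toy_molecules <- function() {
  data.frame(
    name = c("methane", "ethanol", "benzene", "phenol", "aniline",
             "acetic_acid", "caffeine", "aspirin", "ethylbenzene",
             "n_ethylacetamide"),
    smiles = c("C", "CCO", "c1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
               "CC(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
               "CC(=O)Oc1ccccc1C(=O)O", "CCc1ccccc1", "CC(=O)NCC"),
    MW = c(16.043, 46.069, 78.114, 94.113, 93.129, 60.052, 194.194,
           180.159, 106.168, 87.122),
    RBN = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 3L, 1L, 1L),
    nCIC = c(0L, 0L, 1L, 1L, 1L, 0L, 2L, 1L, 1L, 0L),
    nHDon = c(0L, 1L, 0L, 1L, 2L, 1L, 0L, 1L, 0L, 1L),
    nHAcc = c(0L, 1L, 0L, 1L, 1L, 2L, 6L, 4L, 0L, 2L),
    stringsAsFactors = FALSE)
}
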