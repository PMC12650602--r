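# SMOTE oversampling of minority classes; applied to training data only.

#' SMOTE configuration
#'
#' @param k_neighbors Number of same-class nearest neighbours considered
#'   when interpolating (canonical default 5); classes with fewer members
#'   use all available neighbours.
#' @param target_counts Either `"equalize"` (bring every class up to the
#'   majority-class count) or a named 5-vector of target counts, each at
#'   least the current count.
#' @param seed Integer seed driving neighbour and interpolation draws.
#' @return A `smote_config` list.
#' @export
smote_config <- function(k_neighbors = 5L, target_counts = "equalize",
                         seed = 1L) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_counts = target_counts, seed = as.integer(seed)),
            class = "smote_config")
}

#' Linear interpolation between two beats
#'
#' The SMOTE generation primitive: `x + lam * (x_neighbor - x)`.
#'
#' @param x,x_neighbor Equal-length numeric vectors.
#' @param lam Interpolation weight in `[0, 1]`.
#' @return The interpolated vector.
#' @export
smote_interpolate <- function(x, x_neighbor, lam) {
  if (length(x) != length(x_neighbor)) {
    stop("smote_interpolate: length mismatch (", length(x), " vs ",
         length(x_neighbor), ")")
  }
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  x + lam * (x_neighbor - x)
}

#' SMOTE oversampling of minority classes
#'
#' Raises each minority class to its target count by adding synthetic
#' beats: each new beat is a uniform-lambda interpolation between a random
#' class member and one of its `k` nearest same-class neighbours
#' (Euclidean distance on the normalized 188-sample windows). Original
#' rows are preserved verbatim and come first. Datasets whose role is
#' `"val"` or `"test"` refuse balancing: resampling is a training-set-only
#' operation.
#'
#' @param dataset A [beat_dataset()].
#' @param config A [smote_config()].
#' @return A balanced [beat_dataset()]; the provenance step
#'   `"balance_smote"` records the parent indices (`base`, `neighbor`) and
#'   `lam` of every synthetic row.
#' @export
smote_oversample <- function(dataset, config = smote_config()) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (dataset$role %in% c("val", "test")) {
    stop("refusing to balance a '", dataset$role,
         "' dataset: resampling is applied to the training set only")
  }
  counts <- as.integer(dataset$class_counts)
  names(counts) <- names(dataset$class_counts)
  if (identical(config$target_counts, "equalize")) {
    target <- stats::setNames(rep(max(counts), 5L), names(counts))
  } else {
    target <- config$target_counts[names(counts)]
  }
  if (any(target < counts)) {
    stop("target count below current count for class(es): ",
         paste(names(counts)[target < counts], collapse = ", "))
  }
  X <- dataset$beats
  lab <- as.character(dataset$labels)
  new_rows <- list(); new_labs <- character(0)
  parents <- data.frame(class = character(), base = integer(),
                        neighbor = integer(), lam = numeric())
  fallback <- character(0)
  with_seed(config$seed, {
    for (k in names(counts)) {
      need <- target[[k]] - counts[[k]]
      if (need <= 0) next
      idx <- which(lab == k)
      nc <- length(idx)
      if (nc == 0L) next  # absent class: nothing to interpolate from
      if (nc < 2L) {
        # degenerate class: fall back to replication
        rep_idx <- idx[rep_len(seq_len(nc), need)]
        new_rows[[k]] <- X[rep_idx, , drop = FALSE]
        new_labs <- c(new_labs, rep(k, need))
        parents <- rbind(parents, data.frame(class = k, base = rep_idx,
                                             neighbor = rep_idx, lam = 0))
        fallback <- c(fallback, k)
        next
      }
      Xc <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      kk <- min(config$k_neighbors, nc - 1L)
      nn <- t(apply(D, 1L, function(d) order(d)[seq_len(kk)]))
      base <- sample.int(nc, need, replace = TRUE)
      nb_pick <- vapply(base, function(b) nn[b, sample.int(kk, 1L)], integer(1))
      lam <- runif(need)
      syn <- Xc[base, , drop = FALSE] +
        lam * (Xc[nb_pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      new_rows[[k]] <- syn
      new_labs <- c(new_labs, rep(k, need))
      parents <- rbind(parents, data.frame(class = k, base = idx[base],
                                           neighbor = idx[nb_pick], lam = lam))
    }
  })
  if (!length(new_labs)) {
    # already balanced: return row-identical dataset with a no-op record
    prov <- c(dataset$provenance,
              list(prov_step("balance_smote", k = config$k_neighbors,
                             added = 0L, seed = config$seed)))
    out <- beat_dataset(X, lab, provenance = prov, role = dataset$role)
    return(out)
  }
  step <- prov_step("balance_smote", k = config$k_neighbors,
                    added = length(new_labs), seed = config$seed,
                    parents = parents)
  if (length(fallback)) {
    step$replication_fallback <- fallback
    warning("classes with < 2 samples replicated instead of interpolated: ",
            paste(fallback, collapse = ", "))
  }
  beat_dataset(rbind(X, do.call(rbind, new_rows)), c(lab, new_labs),
               provenance = c(dataset$provenance, list(step)),
               role = dataset$role)
}
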