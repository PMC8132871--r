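## Reweighting: recover unbiased (canonical-ensemble) probabilities and
## potentials of mean force from a biased trajectory plus its bias record.
## A frame generated under an added bias V carries unbiased weight
## proportional to exp(+V / kbt); the normalized weighted histogram over a
## collective variable gives p, and F = -kbt * ln p (minimum shifted to 0).

#' Unbiased frame weights from per-frame bias energies
#'
#' `w_i` proportional to `exp(V_i / kbt)`, normalized to sum 1; the maximum
#' bias is subtracted before exponentiation to prevent overflow. Frames with
#' zero bias (e.g. unbiased bootstrap frames) reduce to uniform weighting.
#'
#' @param bias_values per-frame bias energies (same units as `kbt`).
#' @param kbt thermal energy (> 0).
#' @return A `weighted_trajectory`: list with `weights` (sums to 1) and
#'   `kbt`.
#' @export
frame_weights <- function(bias_values, kbt) {
  check_number(kbt, "kbt", lower = 1e-300)
  v <- as.numeric(bias_values)
  if (any(!is.finite(v))) stop_desp("bias values must be finite")
  w <- exp((v - max(v)) / kbt)
  structure(list(weights = w / sum(w), kbt = kbt),
            class = "weighted_trajectory")
}

#' Map bias records onto saved frames
#'
#' Bias blocks start at each record's `step`; interior boundaries follow the
#' half-open convention `[start, end)`, so a frame saved exactly at a
#' boundary inherits the newly started block's value. The final block is
#' closed at `last step + block_length` so the terminal frame of a run keeps
#' the bias that generated it. Frames at steps before the first record
#' (the unbiased bootstrap) get bias 0; frames beyond the final block are an
#' error.
#'
#' @param bias_records data frame with columns `step` and `v_bias` (as
#'   written by [write_bias_tsv()]).
#' @param frame_steps sorted ascending vector of saved-frame step counts.
#' @param block_length steps per bias block; inferred from the record
#'   spacing when `NULL`.
#' @return numeric vector of per-frame bias values.
#' @export
assign_block_bias <- function(bias_records, frame_steps, block_length = NULL) {
  frame_steps <- as.numeric(frame_steps)
  if (is.unsorted(frame_steps))
    stop_desp("frame_steps must be sorted ascending")
  if (nrow(bias_records) == 0L) return(numeric(length(frame_steps)))
  ord <- order(bias_records$step)
  steps <- as.numeric(bias_records$step[ord])
  vb <- as.numeric(bias_records$v_bias[ord])
  if (is.null(block_length)) {
    block_length <- if (length(steps) > 1L) min(diff(steps)) else
      max(frame_steps) - steps[1L]
  }
  end <- steps[length(steps)] + block_length
  if (any(frame_steps > end))
    stop_desp("frame step ", max(frame_steps),
              " beyond the last bias block (ends at ", end, ")")
  ## findInterval with left-closed blocks: index of the block whose start
  ## is <= frame step; 0 means before the first record (bootstrap -> 0).
  idx <- findInterval(frame_steps, steps)
  out <- numeric(length(frame_steps))
  out[idx > 0L] <- vb[idx[idx > 0L]]
  out
}

#' Weighted potential of mean force over one or two collective variables
#'
#' Weighted histogram of the collective-variable series, normalized to a
#' probability `p` per bin; free energy `F = -kbt * ln p`, shifted so the
#' occupied minimum is 0. Unoccupied bins are marked unvisited (`F = NA`),
#' never 0.
#'
#' @param cv_values numeric vector (1D) or two-column matrix / list of two
#'   vectors (2D) of per-frame collective-variable values.
#' @param weights a [frame_weights()] object, or `NULL` for uniform weights.
#' @param bins number of equal-width bins per dimension (default 50), or a
#'   list of explicit break vectors.
#' @param kbt thermal energy; defaults to the weights' `kbt`, or 1.
#' @return A `pmf_grid`: `edges`, `centers`, `p`, `free_energy`, `count`,
#'   `visited` (1D vectors or 2D matrices/lists).
#' @export
pmf <- function(cv_values, weights = NULL, bins = 50L, kbt = NULL) {
  if (is.list(cv_values) && !is.data.frame(cv_values))
    cv_values <- do.call(cbind, cv_values)
  cv <- as.matrix(cv_values)
  ndim <- ncol(cv)
  if (!ndim %in% 1:2) stop_desp("pmf supports 1 or 2 collective variables")
  T_ <- nrow(cv)
  if (is.null(weights))
    weights <- frame_weights(numeric(T_), kbt %||% 1)
  if (length(weights$weights) != T_)
    stop_desp("weight count must equal the number of frames",
              class = "desp_shape_error")
  kbt <- kbt %||% weights$kbt

  edges <- lapply(seq_len(ndim), function(d) {
    if (is.list(bins)) return(bins[[d]])
    r <- range(cv[, d])
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = as.integer(bins) + 1L)
  })
  bin_of <- function(x, br) {
    i <- findInterval(x, br, rightmost.closed = TRUE)
    i[i < 1L | i > length(br) - 1L] <- NA_integer_
    i
  }
  idx <- lapply(seq_len(ndim), function(d) bin_of(cv[, d], edges[[d]]))
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  keep <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  w <- weights$weights[keep]

  if (ndim == 1L) {
    p <- vapply(seq_len(nb[1]), function(b)
      sum(w[idx[[1]][keep] == b]), numeric(1))
  } else {
    p <- matrix(0, nb[1], nb[2])
    flat <- (idx[[2]][keep] - 1L) * nb[1] + idx[[1]][keep]
    acc <- tapply(w, flat, sum)
    p[as.integer(names(acc))] <- acc
  }
  p <- p / sum(p)
  visited <- p > 0
  fe <- ifelse(visited, -kbt * log(pmax(p, .Machine$double.xmin)), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  counts <- if (ndim == 1L)
    vapply(seq_len(nb[1]), function(b)
      sum(idx[[1]][keep] == b), numeric(1))
  else {
    ct <- matrix(0, nb[1], nb[2])
    tab <- table(flat)
    ct[as.integer(names(tab))] <- as.integer(tab)
    ct
  }
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(edges = edges, centers = centers, p = p, free_energy = fe,
                 count = counts, visited = visited, kbt = kbt,
                 ndim = ndim),
            class = "pmf_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("pmf_grid: %dD, %s bins, %d visited, kbt = %g\n", x$ndim,
              paste(vapply(x$centers, length, integer(1)), collapse = " x "),
              sum(x$visited), x$kbt))
  invisible(x)
}

#' Export a 1D or 2D PMF grid as TSV
#'
#' Columns: bin center(s), p, free_energy, count, visited.
#'
#' @param grid a [pmf()] result.
#' @param path output file.
#' @export
write_pmf_tsv <- function(grid, path) {
  if (grid$ndim == 1L) {
    df <- data.frame(center = grid$centers[[1]], p = grid$p,
                     free_energy = grid$free_energy, count = grid$count,
                     visited = grid$visited)
  } else {
    g <- expand.grid(i = seq_along(grid$centers[[1]]),
                     j = seq_along(grid$centers[[2]]))
    df <- data.frame(center_1 = grid$centers[[1]][g$i],
                     center_2 = grid$centers[[2]][g$j],
                     p = grid$p[cbind(g$i, g$j)],
                     free_energy = grid$free_energy[cbind(g$i, g$j)],
                     count = grid$count[cbind(g$i, g$j)],
                     visited = grid$visited[cbind(g$i, g$j)])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
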