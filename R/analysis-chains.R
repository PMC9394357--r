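# Per-chain geometry: periodic unwrapping, P2 orientational order,
# gyration tensor and the shape factor.

#' Unwrap lipid chains across periodic boundaries
#'
#' Walks each chain from its first bead, replacing every consecutive
#' displacement by its minimum image, so per-chain geometry (end-to-end
#' vectors, gyration tensors) is computed on connected coordinates. Water
#' beads are returned unchanged.
#'
#' @param state A [dpd_state()].
#' @return N x 3 matrix of unwrapped positions.
#' @export
unwrap_chains <- function(state) {
  comp <- state$composition
  pos <- state$positions
  if (is.null(comp) || (comp$n1 + comp$n2) == 0) return(pos)
  box <- state$box
  ct <- composition_chain_table(comp)
  for (tp in unique(ct$lipid_type)) {
    sub <- ct[ct$lipid_type == tp, ]
    nb <- sub$n_beads[1]
    if (nb < 2) next
    idx <- rep(sub$first_bead, each = nb) + rep(seq_len(nb) - 1L,
                                                times = nrow(sub))
    # chains-in-rows arrays per coordinate
    for (d in 1:3) {
      m <- matrix(pos[idx, d], nrow = nrow(sub), ncol = nb, byrow = TRUE)
      steps <- m[, -1, drop = FALSE] - m[, -nb, drop = FALSE]
      steps <- steps - box[d] * round(steps / box[d])
      m <- cbind(m[, 1], steps)
      m <- t(apply(m, 1, cumsum))
      pos[idx, d] <- as.vector(t(m))
    }
  }
  pos
}

#' P2 orientational order of a set of vectors
#'
#' `P2 = (3 cos^2 theta - 1)/2` of each vector against a reference axis:
#' 1 for parallel alignment, -0.5 for perpendicular, 0 on average for an
#' isotropic distribution.
#'
#' @param vectors M x 3 matrix of direction vectors (not necessarily
#'   normalised).
#' @param axis Reference axis: `"x"`, `"y"`, `"z"` or a length-3 vector.
#' @return Numeric vector of P2 values (NA for zero-length vectors).
#' @export
#' @examples
#' p2_orientation(rbind(c(0, 0, 2), c(1, 0, 0)))  # 1, -0.5
p2_orientation <- function(vectors, axis = "z") {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  dimnames(vectors) <- NULL
  a <- if (is.character(axis)) {
    diag(3)[match(axis, c("x", "y", "z")), ]
  } else axis / sqrt(sum(axis^2))
  nv <- sqrt(rowSums(vectors^2))
  ct <- as.vector(vectors %*% a) / nv
  ct[nv == 0] <- NA_real_
  (3 * ct^2 - 1) / 2
}

# per-chain sub-chain end-to-end vectors and the binning coordinate of the
# first sub-chain bead
chain_vectors <- function(state, sub_chain = c("head", "tail", "whole"),
                          positions = NULL) {
  sub_chain <- match.arg(sub_chain)
  comp <- state$composition
  if (is.null(comp) || (comp$n1 + comp$n2) == 0) {
    abort("state has no lipid chains")
  }
  if (is.null(positions)) positions <- unwrap_chains(state)
  ct <- composition_chain_table(comp)
  first_off <- ifelse(sub_chain == "tail", ct$n_head, 0L)
  last_off <- ifelse(sub_chain == "head", ct$n_head - 1L, ct$n_beads - 1L)
  i0 <- ct$first_bead + first_off
  i1 <- ct$first_bead + last_off
  if (any(i1 - i0 < 1)) {
    keep <- (i1 - i0) >= 1
    ct <- ct[keep, ]; i0 <- i0[keep]; i1 <- i1[keep]
  }
  list(chain_table = ct,
       vectors = positions[i1, , drop = FALSE] -
         positions[i0, , drop = FALSE],
       first_pos = state$positions[i0, , drop = FALSE])
}

#' P2 order-parameter profile of lipid sub-chains
#'
#' For each chain the end-to-end vector of the selected sub-chain (head
#' block, tail block, or the whole chain) is compared with the reference
#' axis; chains are binned by the wrapped coordinate of the sub-chain's
#' first bead along that axis and the ensemble mean P2 is reported per
#' bin. Zero-length vectors are skipped and counted.
#'
#' @param state A [dpd_state()] or list of states (chains pooled).
#' @param sub_chain `"head"`, `"tail"` or `"whole"`.
#' @param axis `"z"` (membrane normal), `"x"` or `"y"`.
#' @param bin_width Bin width in rc.
#' @return Tibble with `bin`, `coord` (bin midpoint), `p2` (mean),
#'   `n_chains` and `n_skipped`; class `dpd_profile`.
#' @export
order_parameter <- function(state, sub_chain = c("head", "tail", "whole"),
                            axis = "z", bin_width = 0.5) {
  sub_chain <- match.arg(sub_chain)
  states <- if (inherits(state, "dpd_state")) list(state) else state
  d <- match(axis, c("x", "y", "z"))
  box <- states[[1]]$box
  n_bins <- max(2L, round(box[d] / bin_width))
  h <- box[d] / n_bins

  acc_sum <- numeric(n_bins); acc_n <- numeric(n_bins); skipped <- 0
  for (st in states) {
    cv <- chain_vectors(st, sub_chain)
    p2 <- p2_orientation(cv$vectors, axis)
    coordv <- cv$first_pos[, d] %% box[d]
    b <- pmin(floor(coordv / h), n_bins - 1) + 1
    ok <- !is.na(p2)
    skipped <- skipped + sum(!ok)
    acc_sum <- acc_sum + as.vector(tapply(p2[ok], factor(b[ok],
      levels = seq_len(n_bins)), sum, default = 0))
    acc_n <- acc_n + as.vector(table(factor(b[ok],
      levels = seq_len(n_bins))))
  }
  out <- tibble(bin = seq_len(n_bins), coord = (seq_len(n_bins) - 0.5) * h,
                p2 = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
                n_chains = acc_n, n_skipped = skipped)
  class(out) <- c("dpd_profile", class(out))
  out
}

#' Gyration tensor of one chain
#'
#' `Rg2_ab = (1/N) sum_i (r_i,a - rcm,a)(r_i,b - rcm,b)` over the beads of
#' a chain (coordinates must already be unwrapped). The trace is the
#' mean-square radius of gyration.
#'
#' @param chain_positions M x 3 matrix of bead coordinates.
#' @return List with `tensor` (3 x 3), `eigenvalues` (descending,
#'   `L1^2 >= L2^2 >= L3^2`), `rg2` (trace) and `components`
#'   (`Rgxx2`, `Rgyy2`, `Rgzz2`).
#' @export
gyration_tensor <- function(chain_positions) {
  p <- chain_positions
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  dimnames(p) <- NULL
  centred <- sweep(p, 2, colMeans(p))
  g <- crossprod(centred) / nrow(p)
  ev <- sort(eigen(g, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  list(tensor = g, eigenvalues = ev, rg2 = sum(diag(g)),
       components = setNames(diag(g), c("Rgxx2", "Rgyy2", "Rgzz2")))
}

#' Chain shape factor from gyration-tensor eigenvalues
#'
#' `delta = 1 - 3 (L1^2 L2^2 + L2^2 L3^2 + L1^2 L3^2) / (L1^2+L2^2+L3^2)^2`:
#' 0 for a sphere-like mass distribution, 1 for a rod.
#'
#' @param eigenvalues Numeric length-3 vector of gyration-tensor
#'   eigenvalues (any order).
#' @return `delta` in `[0, 1]`; `NA` for an all-zero tensor.
#' @export
#' @examples
#' shape_factor(c(1, 0, 0))  # 1: rod
#' shape_factor(c(1, 1, 1))  # 0: sphere
shape_factor <- function(eigenvalues) {
  stopifnot(length(eigenvalues) == 3, all(eigenvalues >= -1e-12))
  s <- sum(eigenvalues)
  if (s <= 0) return(NA_real_)
  l <- eigenvalues
  1 - 3 * (l[1] * l[2] + l[2] * l[3] + l[1] * l[3]) / s^2
}

#' Ensemble shape factor from pooled gyration eigenvalues
#'
#' The ensemble summary `<delta>` combines the ensemble-averaged
#' eigenvalues `<L1^2>, <L2^2>, <L3^2>` through the shape-factor formula
#' (averaging the eigenvalues before combining them). The per-chain
#' `delta` column of [gyration_chains()] is the companion distribution
#' view; the two differ slightly because the formula is nonlinear.
#'
#' @param gyration A [gyration_chains()] tibble (columns `l1`, `l2`,
#'   `l3`), or a list of states passed through it.
#' @return `<delta>` in `[0, 1]`.
#' @export
mean_shape_factor <- function(gyration) {
  if (!is.data.frame(gyration)) gyration <- gyration_chains(gyration)
  shape_factor(c(mean(gyration$l1), mean(gyration$l2),
                 mean(gyration$l3)))
}

#' Per-chain gyration and shape statistics
#'
#' Unwraps every chain and computes its gyration tensor, diagonal
#' components, sorted eigenvalues and shape factor.
#'
#' @param state A [dpd_state()] or list of states (rows pooled, with a
#'   `time` column distinguishing frames).
#' @return Tibble with `time`, `chain_id`, `lipid_type`, `rg2`, `rgxx2`,
#'   `rgyy2`, `rgzz2`, `l1`, `l2`, `l3` (eigenvalues, descending) and
#'   `delta`.
#' @export
gyration_chains <- function(state) {
  states <- if (inherits(state, "dpd_state")) list(state) else state
  out <- lapply(states, function(st) {
    comp <- st$composition
    ct <- composition_chain_table(comp)
    pos <- unwrap_chains(st)
    rows <- lapply(seq_len(nrow(ct)), function(k) {
      idx <- ct$first_bead[k] + seq_len(ct$n_beads[k]) - 1L
      g <- gyration_tensor(pos[idx, , drop = FALSE])
      c(g$components, l1 = g$eigenvalues[1], l2 = g$eigenvalues[2],
        l3 = g$eigenvalues[3], rg2 = g$rg2,
        delta = shape_factor(g$eigenvalues))
    })
    m <- do.call(rbind, rows)
    tibble(time = st$time, chain_id = ct$chain_id,
           lipid_type = ct$lipid_type,
           rg2 = m[, "rg2"], rgxx2 = m[, "Rgxx2"], rgyy2 = m[, "Rgyy2"],
           rgzz2 = m[, "Rgzz2"], l1 = m[, "l1"], l2 = m[, "l2"],
           l3 = m[, "l3"], delta = m[, "delta"])
  })
  bind_rows(out)
}
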