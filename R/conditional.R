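# Exact stepwise conditional analysis: block partitioning of significant
# variants, add/remove stepwise multiple regression at the study-wide
# threshold, chromosome-level joint refinement, and LD clumping of sentinel
# variants into loci.

#' Study-wide conditional significance threshold
#'
#' Default t-test p-value threshold used by the stepwise conditional
#' analysis (8.31e-9); the meta-analysis stage conventionally uses 5e-9.
#' @export
conditional_p_threshold <- 8.31e-9

#' Partition significant variants into conditional-analysis blocks
#'
#' Splits the genome-wide significant variants of one phenotype into the
#' largest number of blocks such that adjacent blocks are separated by at
#' least `gap` base pairs, then further splits any block exceeding
#' `max_size` variants at its largest internal gaps until every block is
#' within the cap.
#'
#' @param variants Tibble with columns `chrom` and `pos` (sorted within
#'   chromosome), plus any carried columns.
#' @param gap Minimum separation (bp) between adjacent blocks; splits occur
#'   at every inter-variant gap `>= gap`.
#' @param max_size Maximum variants per block.
#' @return The input tibble with a `block` label column; attribute `blocks`
#'   summarises each block (chrom, start, end, n).
#' @export
partition_blocks <- function(variants, gap = 5e6, max_size = 2500) {
  variants <- tibble::as_tibble(variants)
  if (!all(c("chrom", "pos") %in% names(variants))) {
    abort("`variants` needs columns `chrom` and `pos`.")
  }
  split_oversized <- function(pos_idx, pos) {
    if (length(pos_idx) <= max_size) return(list(pos_idx))
    gaps <- diff(pos[pos_idx])
    # split at the largest internal gap; among tied gaps take the most
    # balanced cut so progress is guaranteed
    cand <- which(gaps == max(gaps))
    cut <- cand[which.min(abs(cand - length(pos_idx) / 2))]
    c(split_oversized(pos_idx[seq_len(cut)], pos),
      split_oversized(pos_idx[(cut + 1):length(pos_idx)], pos))
  }
  out <- variants
  out$block <- NA_character_
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    pos <- variants$pos[idx]
    if (is.unsorted(pos)) abort(sprintf("positions unsorted on chromosome %s.", ch))
    grp <- cumsum(c(1, diff(pos) >= gap))
    pieces <- unlist(
      lapply(split(seq_along(idx), grp), split_oversized, pos = pos),
      recursive = FALSE
    )
    k <- 0L
    for (piece in pieces) {
      k <- k + 1L
      out$block[idx[piece]] <- sprintf("%s_%d", ch, k)
    }
  }
  attr(out, "blocks") <- out |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$pos), end = max(.data$pos),
                     n = dplyr::n(), .groups = "drop")
  out
}

# Joint OLS of y on the variants in `M` (column indices of X), with
# intercept. Returns per-variant beta/se/p; aliased (perfectly collinear)
# variants get p = 1 so the removal stage discards them.
ols_joint <- function(X, M, y) {
  Z <- cbind(`(Intercept)` = 1, X[, M, drop = FALSE])
  fit <- stats::lm.fit(Z, y)
  cf <- fit$coefficients
  aliased <- is.na(cf)
  r <- fit$rank
  df <- length(y) - r
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  p1 <- fit$qr$pivot[seq_len(r)]
  Rinv <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
  se <- rep(NA_real_, length(cf))
  se[p1] <- sqrt(diag(Rinv) * sigma2)
  tval <- cf / se
  p <- 2 * pt(-abs(tval), df = df)
  p[aliased] <- 1
  beta <- cf[-1]; sev <- se[-1]; pv <- p[-1]
  beta[is.na(beta)] <- 0
  list(beta = beta, se = sev, p = pv, rss = rss, df = df)
}

# Addition-stage p-values by Frisch-Waugh-Lovell: residualize y and every
# candidate on [1, X_M]; the candidate's coefficient t-test in the
# augmented model equals the t-test of the residual-on-residual regression
# with df = n - |M| - 2.
addition_pvalues <- function(X, M, cand, y) {
  n <- nrow(X)
  qrM <- qr(cbind(1, X[, M, drop = FALSE]))
  ry <- qr.resid(qrM, y)
  RG <- qr.resid(qrM, X[, cand, drop = FALSE])
  d <- colSums(RG^2)
  bn <- as.vector(crossprod(RG, ry))
  beta <- bn / d
  rss0 <- sum(ry^2)
  df <- n - length(M) - 2L
  rss <- rss0 - beta^2 * d
  se <- sqrt(pmax(rss, 0) / df / d)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = df)
  p[d <= .Machine$double.eps * n] <- NA_real_  # numerically collinear with M
  p
}

new_sentinel_set <- function(tbl, n, p_threshold) {
  attr(tbl, "n") <- n
  attr(tbl, "p_threshold") <- p_threshold
  class(tbl) <- c("sentinel_set", class(tbl))
  tbl
}

#' Stepwise conditional selection within a block
#'
#' Identifies a parsimonious set of conditionally independent variants
#' explaining the association signal of a block by stepwise multiple linear
#' regression. The model is seeded with the variant of lowest univariable
#' p-value (provided it passes the threshold); then, repeatedly, the
#' candidate whose coefficient t-test in the augmented model has the lowest
#' p-value is added while that p-value is below the threshold, skipping
#' candidates in high LD (r^2 > `ld_r2_skip`) with any model member; after
#' every addition, members whose drop-one t-test p-value is at or above the
#' threshold are removed, worst first. Convergence occurs when no addition
#' and no removal qualifies; the final joint model is refit and reported.
#'
#' @param G A [geno_matrix()] (or dosage matrix) restricted to one block.
#' @param y Adjusted, inverse-normalized phenotype.
#' @param p_threshold Conditional significance threshold
#'   ([conditional_p_threshold] by default).
#' @param ld_r2_skip Candidates with dosage r^2 above this value with any
#'   model member are never tested for addition.
#' @param max_iter Safety cap on add/remove steps.
#' @return A `sentinel_set`: tibble `id`, `beta`, `se`, `p` (joint-model
#'   estimates), `univ_p`, `order_added`; attributes `n` and `p_threshold`.
#' @export
stepwise_select <- function(G, y, p_threshold = conditional_p_threshold,
                            ld_r2_skip = 0.9, max_iter = 1000L) {
  X <- as_dosage_matrix(G)
  if (ncol(X) == 0) abort("empty block.")
  if (length(y) != nrow(X)) abort("`y` must align with the rows of `G`.")
  if (sd(y) < 1e-12) abort("`y` is constant.")
  ids <- colnames(X) %||% sprintf("v%d", seq_len(ncol(X)))
  sds <- apply(X, 2L, sd)
  poly <- which(sds > 0)
  if (length(poly) == 0) abort("all variants in the block are monomorphic.")
  X <- X[, poly, drop = FALSE]
  ids <- ids[poly]

  sc <- fast_marginal_scan(X, y)
  univ_p <- sc$p
  empty <- new_sentinel_set(
    tibble::tibble(id = character(), beta = double(), se = double(),
                   p = double(), univ_p = double(), order_added = integer()),
    nrow(X), p_threshold
  )
  if (min(univ_p) > p_threshold) return(empty)

  M <- which.min(univ_p)  # ties: first (lowest coordinate, columns in order)
  order_added <- setNames(1L, ids[M])
  steps <- 0L
  next_ord <- 2L
  repeat {
    steps <- steps + 1L
    if (steps > max_iter) abort("stepwise selection failed to converge within `max_iter` steps.")
    cand <- setdiff(seq_len(ncol(X)), M)
    if (length(cand) > 0) {
      r2 <- cor(X[, cand, drop = FALSE], X[, M, drop = FALSE])^2
      cand <- cand[apply(r2, 1L, max) <= ld_r2_skip]
    }
    added <- FALSE
    if (length(cand) > 0) {
      p_add <- addition_pvalues(X, M, cand, y)
      ok <- !is.na(p_add)
      if (any(ok) && min(p_add[ok]) <= p_threshold) {
        best <- cand[ok][which.min(p_add[ok])]
        M <- c(M, best)
        order_added[ids[best]] <- next_ord
        next_ord <- next_ord + 1L
        added <- TRUE
      }
    }
    if (!added) break
    # removal stage: drop worst member while its drop-one p >= threshold
    repeat {
      steps <- steps + 1L
      if (steps > max_iter) abort("stepwise selection failed to converge within `max_iter` steps.")
      jf <- ols_joint(X, M, y)
      if (max(jf$p) < p_threshold) break
      worst <- which.max(jf$p)
      order_added <- order_added[names(order_added) != ids[M[worst]]]
      M <- M[-worst]
      if (length(M) == 0) return(empty)
    }
  }
  jf <- ols_joint(X, M, y)
  keep_order <- order(order_added[ids[M]])
  tbl <- tibble::tibble(
    id = ids[M], beta = unname(jf$beta), se = unname(jf$se), p = unname(jf$p),
    univ_p = univ_p[M], order_added = unname(order_added[ids[M]])
  )[keep_order, ]
  new_sentinel_set(tbl, nrow(X), p_threshold)
}

#' Chromosome-level joint refinement of block selections
#'
#' Places all conditionally selected variants of one chromosome into a
#' single joint model and resumes the stepwise algorithm at the removal
#' stage: members whose drop-one p-value is at or above the threshold are
#' removed, worst first, and additions from the pool of previously selected
#' variants are then reconsidered until convergence. This removes redundant
#' signals that block boundaries kept apart.
#'
#' @param G A [geno_matrix()] (or dosage matrix) covering the chromosome.
#' @param y Adjusted phenotype.
#' @param selected_ids Variant IDs selected across the chromosome's blocks
#'   (no duplicates).
#' @inheritParams stepwise_select
#' @return A `sentinel_set` with joint-model estimates for the surviving
#'   variants.
#' @export
chromosome_joint_refine <- function(G, y, selected_ids,
                                    p_threshold = conditional_p_threshold,
                                    ld_r2_skip = 0.9, max_iter = 1000L) {
  X <- as_dosage_matrix(G)
  ids <- colnames(X)
  if (anyDuplicated(selected_ids)) abort("duplicate variant IDs in `selected_ids`.")
  if (!all(selected_ids %in% ids)) abort("some selected IDs are absent from `G`.")
  if (length(selected_ids) == 0) {
    return(new_sentinel_set(
      tibble::tibble(id = character(), beta = double(), se = double(),
                     p = double(), univ_p = double(), order_added = integer()),
      nrow(X), p_threshold
    ))
  }
  pool <- match(selected_ids, ids)
  Xp <- X[, pool, drop = FALSE]
  pids <- ids[pool]
  M <- seq_along(pool)
  univ_p <- fast_marginal_scan(Xp, y)$p
  steps <- 0L
  # removal first, then the full add/remove alternation over the pool
  repeat {
    repeat {
      steps <- steps + 1L
      if (steps > max_iter) abort("joint refinement failed to converge within `max_iter` steps.")
      jf <- ols_joint(Xp, M, y)
      if (max(jf$p) < p_threshold) break
      M <- M[-which.max(jf$p)]
      if (length(M) == 0) {
        return(new_sentinel_set(
          tibble::tibble(id = character(), beta = double(), se = double(),
                         p = double(), univ_p = double(), order_added = integer()),
          nrow(Xp), p_threshold
        ))
      }
    }
    cand <- setdiff(seq_along(pool), M)
    if (length(cand) > 0) {
      r2 <- cor(Xp[, cand, drop = FALSE], Xp[, M, drop = FALSE])^2
      cand <- cand[apply(r2, 1L, max) <= ld_r2_skip]
    }
    if (length(cand) == 0) break
    p_add <- addition_pvalues(Xp, M, cand, y)
    ok <- !is.na(p_add)
    if (!any(ok) || min(p_add[ok]) > p_threshold) break
    M <- c(M, cand[ok][which.min(p_add[ok])])
  }
  jf <- ols_joint(Xp, M, y)
  new_sentinel_set(
    tibble::tibble(id = pids[M], beta = unname(jf$beta), se = unname(jf$se),
                   p = unname(jf$p), univ_p = univ_p[M],
                   order_added = seq_along(M)),
    nrow(Xp), p_threshold
  )
}

#' Greedy LD clumping of sentinel variants into loci
#'
#' Orders sentinels by association p-value, takes the best remaining one as
#' a locus tag, assigns every remaining sentinel with dosage r^2 above
#' `r2_max_between_tags` to that tag's locus, and recurses. By construction
#' all between-tag pairwise r^2 values are at or below the threshold.
#'
#' @param sentinels Tibble with columns `id` and `p` (variants may recur
#'   across traits; each unique ID is clumped once at its best p).
#' @param G Reference [geno_matrix()] (or dosage matrix) containing every
#'   sentinel.
#' @param r2_max_between_tags Maximum allowed r^2 between locus tags.
#' @return Tibble `id`, `p`, `locus`, `is_tag`, `r2_with_tag`, ordered by
#'   locus then descending r^2.
#' @export
ld_clump <- function(sentinels, G, r2_max_between_tags = 0.8) {
  sentinels <- tibble::as_tibble(sentinels)
  if (!all(c("id", "p") %in% names(sentinels))) {
    abort("`sentinels` needs columns `id` and `p`.")
  }
  X <- as_dosage_matrix(G)
  uniq <- sentinels |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(p = min(.data$p), .groups = "drop") |>
    dplyr::arrange(.data$p)
  missing <- setdiff(uniq$id, colnames(X))
  if (length(missing) > 0) {
    abort(sprintf("sentinel(s) absent from the LD reference: %s.",
                  paste(missing, collapse = ", ")))
  }
  remaining <- uniq
  out <- list()
  while (nrow(remaining) > 0) {
    tag <- remaining$id[1]
    r2 <- as.vector(cor(X[, tag], X[, remaining$id, drop = FALSE]))^2
    member <- r2 > r2_max_between_tags | remaining$id == tag
    out[[length(out) + 1L]] <- tibble::tibble(
      id = remaining$id[member], p = remaining$p[member], locus = tag,
      is_tag = remaining$id[member] == tag, r2_with_tag = r2[member]
    )
    remaining <- remaining[!member, , drop = FALSE]
  }
  dplyr::bind_rows(out)
}
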