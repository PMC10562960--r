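#' Partial-correlation conditional-independence test
#'
#' Tests independence of `x` and `y` given `z` under linearity:
#' `x` and `y` are each regressed on `z` (with intercept), the Pearson
#' correlation `rho` of the two residual vectors is Fisher
#' z-transformed, and `t = atanh(rho) * sqrt(n - 4)` is referred to a
#' standard normal (two-sided). If `x` or `y` is fully explained by `z`
#' (degenerate residuals) the test returns `rho = 0`, `p = 1`.
#'
#' @param x,y,z numeric vectors of common length `n >= 5`.
#' @param n sample count; defaults to `length(x)`.
#' @return `list(rho =, p_value =)`.
#' @export
partial_correlation_test <- function(x, y, z, n = length(x)) {
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 5) stop("partial correlation test needs n >= 5")
  design <- cbind(1, z)
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (sum(rx^2) / n < 1e-12 || sum(ry^2) / n < 1e-12) {
    return(list(rho = 0, p_value = 1))
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  rho <- min(max(rho, -1), 1)
  stat <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15)) * sqrt(n - 1 - 3)
  list(rho = rho, p_value = 2 * stats::pnorm(-abs(stat)))
}

#' Test informational equivalence of two variants
#'
#' Selected variant `R` and candidate `C` are equivalent with respect to
#' the iteration residuals `r` when both conditional independencies
#' hold: `Ind(R; r | C)` and `Ind(r; C | R)`, each accepted when its
#' partial-correlation p-value exceeds `alpha_eq`. Intuitively: given
#' either variant, the other carries no further information about the
#' residuals, so one can substitute the other in the signature.
#'
#' @param R,C column indices of the selected variant and the candidate.
#' @param r residual vector of the model on the variants selected
#'   *before* `R` (see [find_equivalents()]).
#' @param g a [genotype_matrix] or numeric matrix.
#' @param alpha_eq equivalence threshold (p-values must exceed it).
#' @return `list(is_equivalent =, p_RrC =, p_rCR =)`.
#' @export
test_equivalence <- function(R, C, r, g, alpha_eq = 0.05) {
  if (R == C) stop("R and C must be distinct variants")
  X <- dosage_matrix(g)
  r <- as.numeric(r)
  p_RrC <- partial_correlation_test(X[, R], r, X[, C])$p_value
  p_rCR <- partial_correlation_test(r, X[, C], X[, R])$p_value
  list(is_equivalent = (p_RrC > alpha_eq && p_rCR > alpha_eq),
       p_RrC = p_RrC, p_rCR = p_rCR)
}

#' Discover statistically equivalent substitutes for each selected
#' variant
#'
#' For the k-th step of the path with selected variant `R`, the
#' residuals of the model on the first k-1 selected variants are
#' recomputed (excluding `R` itself, so that the tests are
#' non-degenerate), candidates are prescreened by residual correlation
#' (`|cor(C, r)| >= prescreen_fraction * |cor(R, r)|`, a speed
#' heuristic), and [test_equivalence()] is applied to each survivor.
#' Collinear candidates skipped during selection are always in the
#' candidate pool.
#'
#' @param g a [genotype_matrix] or numeric matrix (no missing values).
#' @param path a `selection_path` from [epilogi_select()].
#' @param y the phenotype vector the path was selected on.
#' @param alpha_eq equivalence threshold; default 0.05.
#' @param prescreen_fraction candidates below this fraction of `R`'s
#'   residual correlation are not tested; `0` disables prescreening.
#' @return An object of class `signature_set`: list with
#'   `reference_signature` (variant indices), `reference_ids`,
#'   `classes` (one per step: `list(R =, members = data.frame(C, C_id,
#'   p_RrC, p_rCR))`), `alpha_eq`, and `signature_count =
#'   prod(1 + class sizes)`.
#' @export
find_equivalents <- function(g, path, y, alpha_eq = 0.05,
                             prescreen_fraction = 0.5) {
  stopifnot(inherits(path, "selection_path"))
  X <- dosage_matrix(g)
  y <- as.numeric(y)
  sel <- selected_variants(path)
  if (!length(sel)) stop("selection path is empty: nothing to substitute")
  vids <- variant_ids(g)
  m <- ncol(X)
  classes <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    R <- sel[k]
    fit <- fit_submodel(X, y, sel[seq_len(k - 1L)], task = path$task)
    r <- compute_residuals(fit, y)
    rc <- r - mean(r)
    rn <- sqrt(sum(rc^2))
    pool <- setdiff(seq_len(m), sel)
    members <- data.frame(C = integer(0), C_id = character(0),
                          p_RrC = numeric(0), p_rCR = numeric(0),
                          stringsAsFactors = FALSE)
    if (length(pool) && rn > 1e-12) {
      abs_cor <- function(j) {
        x <- X[, j]
        ss <- sum((x - mean(x))^2)
        if (ss < 1e-12) return(0)
        abs(sum(x * rc)) / (sqrt(ss) * rn)
      }
      cR <- abs_cor(R)
      cors <- abs(as.numeric(crossprod(X[, pool, drop = FALSE], rc)))
      ss <- colSums(X[, pool, drop = FALSE]^2) -
        nrow(X) * colMeans(X[, pool, drop = FALSE])^2
      cors <- ifelse(ss > 1e-12, cors / (sqrt(pmax(ss, 1e-300)) * rn), 0)
      keep <- pool[cors >= prescreen_fraction * cR]
      for (C in keep) {
        tq <- test_equivalence(R, C, r, X, alpha_eq)
        if (tq$is_equivalent) {
          members <- rbind(members, data.frame(
            C = C, C_id = vids[C], p_RrC = tq$p_RrC, p_rCR = tq$p_rCR,
            stringsAsFactors = FALSE))
        }
      }
    }
    classes[[k]] <- list(R = R, R_id = vids[R], members = members)
  }
  structure(list(reference_signature = sel,
                 reference_ids = vids[sel],
                 classes = classes,
                 alpha_eq = alpha_eq,
                 signature_count = prod(1 + vapply(classes, function(cl)
                   nrow(cl$members), numeric(1)))),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  sizes <- vapply(x$classes, function(cl) nrow(cl$members), integer(1))
  cat(sprintf("signature_set: reference of %d variant(s); class sizes [%s]; %g signature(s) total\n",
              length(x$reference_signature), paste(sizes, collapse = ", "),
              x$signature_count))
  invisible(x)
}

#' Enumerate equivalent signatures
#'
#' Deterministic order: the reference signature first, then all
#' signatures with one substitution (in path order, then member order),
#' then two substitutions, and so on; truncated at `limit`. The total
#' number available is `s$signature_count` regardless of truncation.
#' Every signature has the same cardinality as the reference.
#'
#' @param s a `signature_set` from [find_equivalents()].
#' @param limit maximum number of signatures to return (>= 1).
#' @return A list of integer vectors of variant indices.
#' @export
enumerate_signatures <- function(s, limit = 100L) {
  stopifnot(inherits(s, "signature_set"), limit >= 1)
  ref <- s$reference_signature
  sizes <- vapply(s$classes, function(cl) nrow(cl$members), integer(1))
  out <- list(ref)
  subst_pos <- which(sizes > 0)
  n_sub <- 1L
  while (length(out) < limit && n_sub <= length(subst_pos)) {
    # combn(x, m) misreads a scalar x as seq_len(x)
    combos <- if (length(subst_pos) == 1) list(subst_pos) else
      utils::combn(subst_pos, n_sub, simplify = FALSE)
    for (pos in combos) {
      # odometer over member choices, later positions varying fastest
      counts <- sizes[pos]
      choice <- rep(1L, n_sub)
      repeat {
        sig <- ref
        for (i in seq_len(n_sub)) {
          sig[pos[i]] <- s$classes[[pos[i]]]$members$C[choice[i]]
        }
        out[[length(out) + 1L]] <- sig
        if (length(out) >= limit) return(out)
        i <- n_sub
        while (i >= 1L) {
          choice[i] <- choice[i] + 1L
          if (choice[i] <= counts[i]) break
          choice[i] <- 1L
          i <- i - 1L
        }
        if (i < 1L) break
      }
    }
    n_sub <- n_sub + 1L
  }
  out
}
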