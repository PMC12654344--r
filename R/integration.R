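#' Cross-table correlation network with BH correction
#'
#' Correlates every feature of table `a` against every feature of table
#' `b` over the same samples, adjusts the full family of p-values with
#' the Benjamini-Hochberg step-up rule, and marks the pairs passing the
#' conventional network filter `|r| > r_min` and `p < alpha`.
#'
#' @param a,b Tibbles with a `sample_id` column followed by numeric
#'   feature columns (e.g. taxon abundances and metabolite intensities);
#'   sample ids must match in the same order.
#' @param method `"pearson"` or `"spearman"`.
#' @param r_min Absolute-correlation filter (default 0.7).
#' @param alpha Raw p-value filter (default 0.05).
#' @return A tibble with `feature_a`, `feature_b`, `r`, `pvalue`, `q_bh`,
#'   `retained`; filter settings are stored in the `"settings"`
#'   attribute.
#' @export
correlate_features <- function(a, b, method = c("pearson", "spearman"),
                               r_min = 0.7, alpha = 0.05) {
  method <- match.arg(method)
  ma <- omics_matrix(a, "a")
  mb <- omics_matrix(b, "b")
  if (!identical(rownames(ma), rownames(mb))) {
    only_a <- setdiff(rownames(ma), rownames(mb))
    only_b <- setdiff(rownames(mb), rownames(ma))
    rlang::abort(
      paste0(
        "sample ids must match in identical order; only in a: [",
        paste(only_a, collapse = ", "), "]; only in b: [",
        paste(only_b, collapse = ", "), "]"
      ),
      class = "mrpath_validation_error"
    )
  }

  grid <- tidyr::expand_grid(
    feature_a = colnames(ma),
    feature_b = colnames(mb)
  )
  tests <- purrr::map2(grid$feature_a, grid$feature_b, function(fa, fb) {
    ct <- suppressWarnings(
      stats::cor.test(ma[, fa], mb[, fb], method = method, exact = FALSE)
    )
    c(r = unname(ct$estimate), pvalue = ct$p.value)
  })
  out <- grid |>
    dplyr::mutate(
      r = purrr::map_dbl(tests, "r"),
      pvalue = purrr::map_dbl(tests, "pvalue"),
      q_bh = stats::p.adjust(.data$pvalue, method = "BH"),
      retained = abs(.data$r) > r_min & .data$pvalue < alpha
    )
  attr(out, "settings") <- list(method = method, r_min = r_min, alpha = alpha)
  out
}

# sample_id-keyed tibble -> numeric matrix with sample rownames
omics_matrix <- function(tbl, what) {
  check_config(
    is.data.frame(tbl) && "sample_id" %in% names(tbl),
    paste0("table `", what, "` must have a sample_id column")
  )
  feat <- dplyr::select(tbl, -dplyr::any_of(c("sample_id", "group")))
  check_that(purrr::map_lgl(feat, is.numeric),
             paste0("feature columns of `", what, "` must be numeric"))
  check_that(!anyDuplicated(tbl$sample_id),
             paste0("duplicate sample ids in `", what, "`"))
  check_that(!anyDuplicated(names(feat)),
             paste0("duplicate feature ids in `", what, "`"))
  m <- as.matrix(feat)
  rownames(m) <- as.character(tbl$sample_id)
  m
}

#' Mantel test between two distance matrices
#'
#' Correlates the lower-triangle entries of two sample-by-sample distance
#' matrices and assesses significance by simultaneously permuting the
#' rows and columns of the second matrix. The one-sided (greater)
#' p-value uses the add-one correction
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param dist_a,dist_b Square symmetric matrices with zero diagonal (or
#'   `dist` objects), same dimension.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param method Correlation flavor, `"pearson"` (default) or
#'   `"spearman"`.
#' @param exhaustive Enumerate all `n!` sample permutations instead of
#'   sampling (exact test; only allowed for up to 7 samples). The
#'   identity permutation is part of the enumeration, so
#'   `p = #\{r_perm >= r_obs\} / n!`.
#' @return An object of class `mantel_result`: list with `r`, `pvalue`,
#'   `n_perm`, `seed`, `method`, `perm_r` (the permutation distribution).
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1,
                        method = c("pearson", "spearman"),
                        exhaustive = FALSE) {
  method <- match.arg(method)
  da <- as_distance_matrix(dist_a, "dist_a")
  db <- as_distance_matrix(dist_b, "dist_b")
  check_that(nrow(da) == nrow(db), "distance matrices must share dimension")
  check_config(is_single_number(n_perm) && n_perm >= 1, "`n_perm` must be >= 1")
  check_config(is_single_number(seed), "`seed` must be a single integer")

  lt <- lower.tri(da)
  r_obs <- stats::cor(da[lt], db[lt], method = method)
  n <- nrow(da)
  if (exhaustive) {
    check_config(n <= 7, "exhaustive enumeration supported for <= 7 samples")
    perms <- permutations_of(n)
    perm_r <- vapply(perms, function(p) {
      stats::cor(da[lt], db[p, p][lt], method = method)
    }, numeric(1))
    return(structure(
      list(r = r_obs, pvalue = mean(perm_r >= r_obs),
           n_perm = length(perms), seed = as.integer(seed),
           method = method, perm_r = perm_r),
      class = "mantel_result"
    ))
  }
  perm_r <- with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(da[lt], db[p, p][lt], method = method)
    }, numeric(1))
  })
  pvalue <- (1 + sum(perm_r >= r_obs)) / (n_perm + 1)

  structure(
    list(r = r_obs, pvalue = pvalue, n_perm = n_perm,
         seed = as.integer(seed), method = method, perm_r = perm_r),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %d permutations): r = %.4f, p = %.4g\n",
              x$method, x$n_perm, x$r, x$pvalue))
  invisible(x)
}

# all permutations of 1..n (iterative insertion construction)
permutations_of <- function(n) {
  perms <- list(1L)
  for (k in seq_len(n)[-1]) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
    }), recursive = FALSE)
  }
  perms
}

as_distance_matrix <- function(d, what) {
  if (inherits(d, "dist")) {
    d <- as.matrix(d)
  }
  check_that(is.matrix(d) && nrow(d) == ncol(d),
             paste0("`", what, "` must be a square matrix or dist object"))
  check_that(abs(d - t(d)) < 1e-8, paste0("`", what, "` must be symmetric"))
  check_that(abs(diag(d)) < 1e-8, paste0("`", what, "` must have zero diagonal"))
  d
}

#' Euclidean distance matrix from an omics table
#'
#' @param tbl Tibble with `sample_id` (and optionally `group`) plus
#'   numeric features.
#' @return Square symmetric matrix with sample-id dimnames.
#' @export
dist_euclidean <- function(tbl) {
  as.matrix(stats::dist(omics_matrix(tbl, "tbl")))
}

#' Bray-Curtis dissimilarity matrix from an omics table
#'
#' Thin wrapper over [vegan::vegdist()]; values must be nonnegative
#' (abundances).
#'
#' @inheritParams dist_euclidean
#' @return Square symmetric matrix with sample-id dimnames.
#' @export
dist_bray_curtis <- function(tbl) {
  m <- omics_matrix(tbl, "tbl")
  check_that(m >= 0, "Bray-Curtis requires nonnegative abundances")
  as.matrix(vegan::vegdist(m, method = "bray"))
}
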