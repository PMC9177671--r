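#' Select extreme-phenotype bulks
#'
#' Quantitative mode returns the `n_per_bulk` highest- and lowest-valued
#' individuals; ties at a selection boundary are broken by a stable sort on
#' (value, id) so membership is deterministic and invariant to input order.
#' Categorical mode returns `n_per_bulk` members per class; an over-sized
#' class is down-sampled deterministically under `seed`.
#'
#' @param phenotypes data.frame with columns `id` and `trait`.
#' @param trait Column name of the trait.
#' @param n_per_bulk Plants per bulk (default 15, the study design).
#' @param mode `"quantitative"` or `"categorical"`.
#' @param high_class,low_class For categorical mode, the class labels mapped
#'   to the high- and low-trait bulks (the high bulk is the one expected to
#'   match the reference parent, e.g. the obcordate class).
#' @param seed Seed used only to down-sample an over-sized class.
#' @return list(high = ids, low = ids), disjoint, each of length
#'   `n_per_bulk`.
#' @export
select_extreme_bulks <- function(phenotypes, trait, n_per_bulk = 15L,
                                 mode = c("quantitative", "categorical"),
                                 high_class = NULL, low_class = NULL,
                                 seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(c("id", trait) %in% names(phenotypes)), n_per_bulk >= 1L)
  x <- phenotypes[[trait]]
  ids <- as.character(phenotypes$id)
  if (anyDuplicated(ids)) stop("duplicate individual ids")

  if (mode == "quantitative") {
    ok <- !is.na(x)
    if (sum(ok) < 2L * n_per_bulk) {
      stop("need at least ", 2L * n_per_bulk, " phenotyped individuals")
    }
    ord <- order(x[ok], ids[ok])  # stable tie-break on id
    sorted_ids <- ids[ok][ord]
    low <- sorted_ids[seq_len(n_per_bulk)]
    high <- sorted_ids[seq(length(sorted_ids) - n_per_bulk + 1L,
                           length(sorted_ids))]
  } else {
    if (is.null(high_class) || is.null(low_class)) {
      stop("categorical mode needs high_class and low_class labels")
    }
    pick <- function(cls) {
      members <- sort(ids[!is.na(x) & x == cls])
      if (length(members) < n_per_bulk) {
        stop("class '", cls, "' has fewer than ", n_per_bulk, " members")
      }
      if (length(members) > n_per_bulk) {
        members <- local_seed(
          derive_seed(seed, paste0("bulk_class_", cls)),
          sort(sample(members, n_per_bulk))
        )
      }
      members
    }
    high <- pick(high_class)
    low <- pick(low_class)
  }
  stopifnot(length(intersect(high, low)) == 0L)
  list(high = high, low = low)
}

#' Chi-square goodness-of-fit test for Mendelian segregation
#'
#' Pearson test of observed two-class counts against an expected ratio
#' (e.g. 3:1 for a recessive trait in an F2), df = 1, no continuity
#' correction.
#'
#' @param observed Integer vector of length 2 (count_classA, count_classB).
#' @param expected_ratio Numeric length-2 ratio, default `c(3, 1)`.
#' @return list(statistic, df, p_value, expected).
#' @export
#' @examples
#' segregation_chi_square(c(75, 25))          # exact 3:1, chi-square 0
#' segregation_chi_square(c(90, 10), c(1, 1)) # chi-square 64
segregation_chi_square <- function(observed, expected_ratio = c(3, 1)) {
  stopifnot(length(observed) == 2L, all(observed >= 0),
            length(expected_ratio) == 2L, all(expected_ratio > 0))
  if (sum(observed) == 0) stop("zero total count")
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = expected_ratio / sum(expected_ratio),
                      correct = FALSE)
  )
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = unname(ht$expected))
}
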