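## Proportional stratified sample design: exact quotas n_i = N_i / N * n,
## integerized by largest remainder (Hamilton) so the allocations always sum
## to n, and seeded without-replacement draws from an index sheet.

#' Proportional allocation of a sample across strata
#'
#' Splits a total sample size `n` across strata in proportion to the stratum
#' sizes `N_i / N`. Exact quotas are integerized by the largest-remainder
#' rule: floors are assigned first and the remaining units go to the largest
#' fractional remainders (ties broken by larger stratum, then name), so the
#' allocation always sums to `n` and equals the exact quotas whenever those
#' are integers. Should an allocation ever exceed its stratum size it is
#' capped and the overflow redistributed by remainder order.
#'
#' For the canonical two-stratum design -- a population of 600 split 540
#' (polyp) / 60 (no polyp) with `n = 150` -- the allocation is 135 and 15.
#'
#' @param strata Named numeric vector of stratum sizes, or a two-column data
#'   frame (`stratum`, `size`).
#' @param n Required total sample size, `0 <= n <= sum(sizes)`.
#' @return A `strata_allocation` tibble: `stratum`, `size`, `quota`
#'   (exact), `allocation` (integer); attributes `N` and `n`.
#' @examples
#' allocate_proportional(c(polyp = 540, no_polyp = 60), 150)
#' @export
allocate_proportional <- function(strata, n) {
  if (is.data.frame(strata)) {
    sizes <- setNames(as.numeric(strata[[2]]), as.character(strata[[1]]))
  } else {
    sizes <- strata
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    names(sizes) <- paste0("stratum_", seq_along(sizes))
  }
  if (any(sizes < 0) || any(sizes != round(sizes))) {
    abort("stratum sizes must be non-negative integers",
          class = "ctcurate_sampling_error")
  }
  N <- sum(sizes)
  if (N <= 0) {
    abort("total population size must be positive", class = "ctcurate_sampling_error")
  }
  if (n < 0 || n != round(n)) {
    abort("n must be a non-negative integer", class = "ctcurate_sampling_error")
  }
  if (n > N) {
    abort(sprintf("infeasible design: n = %d exceeds population N = %d", n, N),
          class = "ctcurate_sampling_error")
  }
  quota <- sizes / N * n
  alloc <- floor(quota + 1e-9)
  remainder <- quota - alloc
  short <- as.integer(round(n - sum(alloc)))
  if (short > 0) {
    ord <- order(-remainder, -sizes, names(sizes))
    bump <- head(ord, short)
    alloc[bump] <- alloc[bump] + 1
  }
  ## defensive cap: n_i can never exceed N_i under proportional quotas, but a
  ## capped-and-redistribute pass keeps the invariant under any rounding
  over <- alloc > sizes
  while (any(over)) {
    excess <- sum(alloc[over] - sizes[over])
    alloc[over] <- sizes[over]
    roomy <- which(alloc < sizes)
    ord <- roomy[order(-remainder[roomy])]
    for (i in ord) {
      if (excess <= 0) break
      add <- min(excess, sizes[i] - alloc[i])
      alloc[i] <- alloc[i] + add
      excess <- excess - add
    }
    over <- alloc > sizes
  }
  out <- tibble::tibble(stratum = names(sizes), size = as.integer(sizes),
                        quota = unname(quota), allocation = as.integer(alloc))
  attr(out, "N") <- as.integer(N)
  attr(out, "n") <- as.integer(n)
  class(out) <- c("strata_allocation", class(out))
  out
}

#' Draw a stratified sample from an index sheet
#'
#' Uniform without-replacement draw of `allocation` rows per stratum, using
#' one explicit integer seed and no global RNG state (the caller's
#' `.Random.seed` is restored on exit). Strata are drawn in sorted stratum
#' order so equal seeds give identical samples.
#'
#' @param sheet An `index_sheet` (or any data frame).
#' @param allocation A `strata_allocation` (see [allocate_proportional()]).
#' @param stratum_col Column of `sheet` holding the stratum label of each
#'   row, e.g. `"Polyp found"`.
#' @param seed Integer seed for the draw.
#' @return The sampled rows (original order preserved), with
#'   `sum(allocation)` rows.
#' @export
draw_sample <- function(sheet, allocation, stratum_col, seed) {
  check_columns(sheet, stratum_col)
  if (!all(c("stratum", "allocation") %in% names(allocation))) {
    abort("allocation must carry 'stratum' and 'allocation' columns",
          class = "ctcurate_sampling_error")
  }
  labels <- as.character(sheet[[stratum_col]])
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  take <- integer(0)
  ord <- order(allocation$stratum)
  for (i in ord) {
    want <- allocation$allocation[i]
    rows <- which(!is.na(labels) & labels == allocation$stratum[i])
    if (length(rows) < want) {
      abort(sprintf("stratum '%s' has %d eligible row(s) but needs %d",
                    allocation$stratum[i], length(rows), want),
            class = "ctcurate_sampling_error")
    }
    if (want > 0) {
      take <- c(take, rows[sample.int(length(rows), want)])
    }
  }
  sheet[sort(take), , drop = FALSE]
}
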