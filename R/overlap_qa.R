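# ROI delineation quality control via the Dice overlap coefficient,
# comparing e.g. an atlas-projected region against a manually defined one.

#' Dice overlap coefficient between two label masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, in `[0, 1]`; 1 for identical
#' non-empty masks, 0 for disjoint ones. Masks must live in the same index
#' space, and at least one must be non-empty.
#'
#' @param a,b [label_mask()] objects with identical `space_dim`.
#' @return The Dice coefficient.
#' @examples
#' m <- simulate_mask_pair(3, 5, 2, seed = 1)
#' dice(m$a, m$b)  # 2*2 / (3+5) = 0.5
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  if (!identical(a$space_dim, b$space_dim)) {
    stop("masks live in different index spaces (",
         paste(a$space_dim, collapse = "x"), " vs ",
         paste(b$space_dim, collapse = "x"), ")", call. = FALSE)
  }
  na <- length(a$indices); nb <- length(b$indices)
  if (na + nb == 0L) stop("both masks are empty", call. = FALSE)
  2 * length(intersect(a$indices, b$indices)) / (na + nb)
}

#' Dice coefficients for a batch of mask pairs, with group summaries
#'
#' @param pairs A list; each element is a list with elements `a` and `b`
#'   ([label_mask()]s) and optionally `id`, `hemisphere` and `group`
#'   (e.g. `"infant"` / `"adult"`).
#' @return A `dice_table` object: `table` (one row per pair: `id`,
#'   `hemisphere`, `group`, `dice`) and `summary` (per group: `n`, `mean`,
#'   `sd`; `sd` is 0 by convention and flagged when `n = 1`).
#' @export
dice_table <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    data.frame(
      id = if (is.null(pr$id)) sprintf("pair%02d", i) else pr$id,
      hemisphere = if (is.null(pr$hemisphere)) NA_character_ else pr$hemisphere,
      group = if (is.null(pr$group)) "all" else pr$group,
      dice = dice(pr$a, pr$b),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(tab, tab$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean = mean(g$dice),
               sd = if (nrow(g) > 1) stats::sd(g$dice) else 0,
               single_pair = nrow(g) == 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(table = tab, summary = summary), class = "dice_table")
}

#' @export
print.dice_table <- function(x, ...) {
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("%s: Dice %.3f +/- %.3f (mean +/- SD, n = %d%s)\n",
                s$group, s$mean, s$sd, s$n,
                if (s$single_pair) ", SD 0 by convention" else ""))
  }
  invisible(x)
}

#' Write a Dice batch as TSV
#'
#' @param x A `dice_table`.
#' @param path Output TSV path; a summary block is appended after a blank
#'   line marker column.
#' @return `path`, invisibly.
#' @export
write_dice_table <- function(x, path) {
  stopifnot(inherits(x, "dice_table"))
  tab <- x$table
  tab$dice <- sprintf("%.17g", tab$dice)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
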