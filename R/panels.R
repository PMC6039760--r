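#' SNP panel
#'
#' An ordered set of SNP ids selected for genotyping, with a provenance tag
#' recording how it was built.
#'
#' @param name panel label, e.g. `"RF3000"`, `"Even1000"`, `"ALL"`.
#' @param snp_ids character vector of unique SNP ids.
#' @param provenance one of `"vim_topk"`, `"vim_positive"`,
#'   `"evenly_spaced"`, `"all"`.
#' @return list of class `snp_panel`.
#' @export
snp_panel <- function(name, snp_ids,
                      provenance = c("vim_topk", "vim_positive",
                                     "evenly_spaced", "all")) {
  provenance <- match.arg(provenance)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(snp_ids)) stop_("panel snp ids must be unique")
  structure(list(name = name, snp_ids = snp_ids, provenance = provenance),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel '%s': %d SNPs (%s)\n", x$name, length(x$snp_ids),
              x$provenance))
  invisible(x)
}

#' Top-k panel from a variable importance table
#'
#' The `k` best-ranked SNPs, ordered by rank (ties already resolved by
#' genome order inside the [vim_table()]).
#'
#' @param v a [vim_table()].
#' @param k panel size, `1 <= k <= m`.
#' @param name optional panel label.
#' @return a [snp_panel()] of exactly `k` SNPs.
#' @export
top_k <- function(v, k, name = NULL) {
  m <- nrow(v)
  if (k < 1L || k > m) stop_("k must lie in [1, ", m, "]")
  ids <- v$snp_id[order(v$rank)][seq_len(k)]
  snp_panel(name %||% paste0(attr(v, "method"), "_top", k), ids, "vim_topk")
}

#' Positive-importance panel
#'
#' All SNPs with importance strictly greater than 0, ordered by rank. An
#' empty result is allowed (with a warning).
#'
#' @param v a [vim_table()].
#' @param name optional panel label.
#' @return a [snp_panel()].
#' @export
positive_set <- function(v, name = NULL) {
  keep <- v[v$score > 0, , drop = FALSE]
  if (nrow(keep) == 0L)
    warning("no SNPs with positive importance", call. = FALSE)
  ids <- keep$snp_id[order(keep$rank)]
  snp_panel(name %||% paste0(attr(v, "method"), "_positive"), ids,
            "vim_positive")
}

#' Evenly spaced baseline panel
#'
#' Selects SNPs at regular marker-index intervals along genome order:
#' 0-based indices `floor(j * (m - 1) / (k - 1))` for `j = 0..k-1`, so the
#' first and last SNP are always included. Purely a function of the map —
#' independent of any importance table — and deterministic. With
#' `by_bp = TRUE`, markers nearest to an equal-base-pair grid are chosen
#' per chromosome instead (panel sizes then apportioned by chromosome
#' length).
#'
#' @param map genome-ordered SNP map (sorted by chromosome, then position).
#' @param k panel size, `2 <= k <= m`.
#' @param by_bp select by physical spacing instead of marker index.
#' @param name optional panel label.
#' @return a [snp_panel()].
#' @export
evenly_spaced <- function(map, k, by_bp = FALSE, name = NULL) {
  m <- nrow(map)
  if (k < 2L) stop_("k must be >= 2")
  if (k > m) stop_("k must be <= ", m)
  if (!by_bp) {
    idx <- floor((seq_len(k) - 1) * (m - 1) / (k - 1)) + 1L
    ids <- map$snp_id[idx]
  } else {
    chroms <- unique(map$chrom)
    span <- vapply(chroms, function(cc) {
      pp <- map$pos_bp[map$chrom == cc]
      diff(range(pp)) + 1
    }, numeric(1))
    alloc <- pmax(1L, round(k * span / sum(span)))
    while (sum(alloc) != k) {
      i <- if (sum(alloc) > k) which.max(alloc) else which.min(alloc)
      alloc[i] <- alloc[i] + sign(k - sum(alloc))
    }
    ids <- unlist(lapply(seq_along(chroms), function(i) {
      sub <- map[map$chrom == chroms[i], , drop = FALSE]
      gridpts <- seq(min(sub$pos_bp), max(sub$pos_bp), length.out = alloc[i])
      sel <- unique(vapply(gridpts, function(gp)
        which.min(abs(sub$pos_bp - gp)), integer(1)))
      sub$snp_id[sel]
    }))
  }
  snp_panel(name %||% paste0("Even", k), unique(ids), "evenly_spaced")
}

#' Read SNP ids from a one-column panel file
#'
#' Lines starting with `#` (provenance comments) and a `snp_id` header are
#' skipped.
#'
#' @param path panel file path.
#' @return character vector of SNP ids.
#' @export
read_panel_ids <- function(path) {
  x <- readLines(path)
  x <- x[!grepl("^#", x) & nzchar(x)]
  setdiff(x, "snp_id")
}

#' Venn-region overlap counts between panels
#'
#' For 2 or 3 panels sharing a SNP universe, counts every exclusive Venn
#' region; counts reconcile with panel sizes by inclusion-exclusion.
#'
#' @param panels list of 2 or 3 [snp_panel()] objects.
#' @return data.frame with columns `region` (panel names joined by `&`,
#'   exclusive regions) and `count`; panel sizes are in attribute `sizes`.
#' @export
overlap_counts <- function(panels) {
  stopifnot(is.list(panels), length(panels) %in% c(2L, 3L))
  sets <- lapply(panels, `[[`, "snp_ids")
  nm <- vapply(panels, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_("panel names must be distinct")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(r) paste(nm[r], collapse = " & "))
  combos <- unlist(lapply(seq_along(nm), function(sz)
    utils::combn(nm, sz, paste, collapse = " & ")))
  counts <- vapply(combos, function(cc) sum(key == cc), integer(1))
  out <- data.frame(region = combos, count = as.integer(counts),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "sizes") <- setNames(lengths(sets), nm)
  out
}
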