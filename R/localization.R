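# Region labelling on the ten-region atlas and laterality concordance.

#' Label clusters with atlas regions
#'
#' Each cluster receives the set of atlas regions its voxels intersect
#' (`regions` column, comma-joined in decreasing voxel-count order -- a
#' cluster straddling two sectors is classified into multiple areas) and the
#' single region containing its peak voxel (`peak_region`). Clusters lying
#' entirely outside the atlas are labelled `"unclassified"` with a warning.
#'
#' @param clusters A `cluster_set` on the template grid.
#' @param template A [make_template()] object (or any list with `atlas` and
#'   `label_table`).
#' @return The `cluster_set` with `regions` and `peak_region` columns
#'   filled in.
#' @export
localize_clusters <- function(clusters, template) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (nrow(clusters) == 0L) return(clusters)
  atlas <- template$atlas
  lt <- template$label_table
  vox <- attr(clusters, "voxels")
  pk <- attr(clusters, "peak_vox")
  name_of <- function(lab) lt$name[match(lab, lt$label)]
  regions <- character(nrow(clusters))
  peak_region <- character(nrow(clusters))
  unclassified <- FALSE
  for (i in seq_len(nrow(clusters))) {
    labs <- atlas[vox[[i]]]
    labs <- labs[labs > 0L]
    if (!length(labs)) {
      regions[i] <- "unclassified"
      unclassified <- TRUE
    } else {
      tab <- sort(table(labs), decreasing = TRUE)
      regions[i] <- paste(name_of(as.integer(names(tab))), collapse = ",")
    }
    pl <- atlas[pk[i]]
    peak_region[i] <- if (pl > 0L) name_of(pl) else "unclassified"
  }
  if (unclassified)
    warning("cluster(s) entirely outside the atlas labelled 'unclassified'",
            call. = FALSE)
  clusters$regions <- regions
  clusters$peak_region <- peak_region
  clusters
}

#' Laterality (or region) concordance between two readings
#'
#' Pairs with `"none"` (or `NA`) on either side are excluded from the
#' evaluable denominator; the proportion of evaluable pairs that agree is
#' reported as an integer percent, rounded half away from zero.
#'
#' @param a,b Character vectors of per-case verdicts (`"left"`, `"right"`,
#'   `"none"`, or region names; `NA` is treated as `"none"`). Alternatively
#'   `a` may be a two-column data frame.
#' @return An object of class `concordance_report`: `n_evaluable`,
#'   `n_concordant`, `proportion_percent`.
#' @export
concordance <- function(a, b = NULL) {
  if (is.null(b)) {
    stopifnot(is.data.frame(a), ncol(a) >= 2L)
    b <- a[[2L]]
    a <- a[[1L]]
  }
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length", call. = FALSE)
  a[is.na(a)] <- "none"; b[is.na(b)] <- "none"
  evaluable <- a != "none" & b != "none"
  n_eval <- sum(evaluable)
  if (n_eval == 0L)
    stop("undefined proportion: no evaluable pairs (all contain 'none')",
         call. = FALSE)
  n_conc <- sum(a[evaluable] == b[evaluable])
  structure(list(n_evaluable = n_eval,
                 n_concordant = n_conc,
                 proportion_percent = as.integer(
                   round_half_away(100 * n_conc / n_eval))),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d of %d evaluable pairs (%d%%)\n",
              x$n_concordant, x$n_evaluable, x$proportion_percent))
  invisible(x)
}
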