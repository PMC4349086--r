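# Per-sex ranking and top/bottom selection on relative wing size, plus
# storage-well bookkeeping and CSV-based exclusions (the software half of
# the sorting mechanism).

#' Relative wing size
#'
#' Wing size normalized to body size. The criterion is a string
#' `"num/den^p"` over measured trait columns; the default `"wa/sw^2"`
#' (wing area over squared shoulder width) is dimensionless, so it is
#' invariant under overall body scale. Alternatives such as `"wl/sw"` or
#' `"wl/iod"` work the same way.
#'
#' @param record one-row data.frame (or list) with the trait fields.
#' @param criterion criterion string.
#' @return numeric score, or `NA` (with a warning) when a required trait is
#'   missing or the denominator is not positive.
#' @export
relative_wing_size <- function(record, criterion = "wa/sw^2") {
  cr <- parse_criterion(criterion)
  num <- record[[cr$num]]
  den <- record[[cr$den]]
  if (is.null(num) || is.null(den) || !is.finite(num) || !is.finite(den)) {
    warning("missing trait for criterion ", criterion)
    return(NA_real_)
  }
  if (den <= 0) {
    warning("nonpositive denominator for criterion ", criterion)
    return(NA_real_)
  }
  num / den^cr$exponent
}

parse_criterion <- function(criterion) {
  m <- regmatches(criterion,
                  regexec("^\\s*(\\w+)\\s*/\\s*(\\w+)\\s*(\\^\\s*([0-9.]+))?\\s*$",
                          criterion))[[1]]
  if (length(m) == 0) stop("cannot parse criterion '", criterion, "'")
  list(num = m[2], den = m[3],
       exponent = if (nzchar(m[5])) as.numeric(m[5]) else 1)
}

#' Score a measurement table
#'
#' Adds a `relative_wing_size` column computed row-wise by
#' [relative_wing_size()].
#'
#' @param records measurement data.frame (e.g. from [analyze_batch()]).
#' @param criterion criterion string, see [relative_wing_size()].
#' @export
score_records <- function(records, criterion = "wa/sw^2") {
  records$relative_wing_size <- vapply(seq_len(nrow(records)), function(i) {
    suppressWarnings(relative_wing_size(as.list(records[i, ]), criterion))
  }, numeric(1))
  records
}

#' Apply well exclusions from a CSV
#'
#' Marks records whose `well_index` appears in the exclusion table (columns
#' `well_index`, optional `reason`); excluded records are never selected.
#' Unknown well indices give a warning and are ignored.
#'
#' @param records measurement data.frame with a `well_index` column.
#' @param exclusion_csv path to the CSV, or a data.frame.
#' @return records with updated `excluded` / `exclusion_reason` columns.
#' @export
apply_exclusions <- function(records, exclusion_csv) {
  excl <- if (is.data.frame(exclusion_csv)) exclusion_csv
          else utils::read.csv(exclusion_csv)
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  if (!"exclusion_reason" %in% names(records)) {
    records$exclusion_reason <- ""
  }
  if (nrow(excl) == 0) return(records)
  if (!"well_index" %in% names(excl)) stop("exclusion table needs well_index")
  for (i in seq_len(nrow(excl))) {
    j <- which(records$well_index == excl$well_index[i])
    if (length(j) == 0) {
      warning("unknown well_index ", excl$well_index[i], " in exclusions")
      next
    }
    records$excluded[j] <- TRUE
    records$exclusion_reason[j] <-
      if ("reason" %in% names(excl)) as.character(excl$reason[i]) else "excluded"
  }
  records
}

#' Select top and bottom individuals per sex
#'
#' Excluded and unknown-sex records are removed, the rest are sorted per
#' sex by descending score (ties broken by `fly_id`, so selection is
#' deterministic); the first `n_top` form the top group and the last
#' `n_bottom` the bottom group. If fewer records are available than
#' requested, all are selected with a warning.
#'
#' @param records scored measurement data.frame (see [score_records()]),
#'   with columns `well_index`, `fly_id`, `sex`, `relative_wing_size` and
#'   optionally `excluded`.
#' @param n_top,n_bottom selected counts per sex.
#' @return object of class `selection_result`: per-sex lists
#'   `selected_top` / `selected_bottom` of well indices, plus a `table`
#'   data.frame (`well_index`, `fly_id`, `sex`, `score`, `group`).
#' @export
select_extremes <- function(records, n_top, n_bottom) {
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  pool <- records[!records$excluded &
                    records$sex %in% c("male", "female") &
                    is.finite(records$relative_wing_size), , drop = FALSE]
  top <- list(); bottom <- list(); rows <- list()
  for (sx in c("female", "male")) {
    sub <- pool[pool$sex == sx, , drop = FALSE]
    sub <- sub[order(-sub$relative_wing_size, sub$fly_id), , drop = FALSE]
    n <- nrow(sub)
    nt <- n_top; nb <- n_bottom
    if (nt + nb > n) {
      if (n > 0) {
        warning("fewer ", sx, "s available (", n, ") than requested (",
                nt + nb, "); selecting all")
      }
      nt <- min(nt, n); nb <- min(nb, n - nt)
    }
    ti <- if (nt > 0) seq_len(nt) else integer(0)
    bi <- if (nb > 0) seq(n - nb + 1, n) else integer(0)
    top[[sx]] <- sub$well_index[ti]
    bottom[[sx]] <- sub$well_index[bi]
    if (length(ti)) {
      rows[[length(rows) + 1]] <- data.frame(
        well_index = sub$well_index[ti], fly_id = sub$fly_id[ti], sex = sx,
        score = sub$relative_wing_size[ti], group = "top")
    }
    if (length(bi)) {
      rows[[length(rows) + 1]] <- data.frame(
        well_index = sub$well_index[bi], fly_id = sub$fly_id[bi], sex = sx,
        score = sub$relative_wing_size[bi], group = "bottom")
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well_index = integer(0), fly_id = character(0),
               sex = character(0), score = numeric(0), group = character(0))
  if (nrow(tab) == 0 && n_top + n_bottom > 0) {
    warning("no selectable records (all excluded, unknown-sex or unscored)")
  }
  structure(list(selected_top = top, selected_bottom = bottom, table = tab),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  for (sx in names(x$selected_top)) {
    cat(sprintf("%s: top wells [%s], bottom wells [%s]\n", sx,
                paste(x$selected_top[[sx]], collapse = ", "),
                paste(x$selected_bottom[[sx]], collapse = ", ")))
  }
  invisible(x)
}
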