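#' Construct a time-resolved trait tensor
#'
#' Holds line-level phenotype trajectories as a k lines x p traits x T
#' timepoints array, together with the calendar axis (days after sowing)
#' and its partition into blocks of consecutive measurement days. Gaps in
#' the calendar (a day difference greater than one) delimit blocks, as in
#' phenotyping designs that image five days a week.
#'
#' @param values numeric array `k x p x T`.
#' @param line_ids,trait_ids,time_axis identifiers for the three axes;
#'   `time_axis` must be strictly increasing integer days.
#' @param blocks optional list of integer index vectors partitioning
#'   `1:T` into consecutive runs; inferred from `time_axis` when `NULL`.
#' @param allow_missing keep `NA` values (to be mean-imputed later) instead
#'   of raising an error.
#' @return An object of class `trait_tensor`.
#' @export
trait_tensor <- function(values, line_ids = NULL, trait_ids = NULL,
                         time_axis = NULL, blocks = NULL,
                         allow_missing = FALSE) {
  stopifnot(length(dim(values)) == 3)
  dn <- dimnames(values)
  line_ids <- as.character(line_ids %||% dn[[1]] %||% paste0("line", seq_len(dim(values)[1])))
  trait_ids <- as.character(trait_ids %||% dn[[2]] %||% paste0("trait", seq_len(dim(values)[2])))
  if (is.null(time_axis)) {
    time_axis <- if (!is.null(dn[[3]])) as.integer(dn[[3]]) else seq_len(dim(values)[3])
  }
  time_axis <- as.integer(time_axis)
  if (any(diff(time_axis) <= 0)) abort("time_axis must be strictly increasing")
  Tn <- length(time_axis)
  if (dim(values)[3] != Tn) abort("time_axis length does not match values")
  if (is.null(blocks)) blocks <- infer_blocks(time_axis)
  validate_blocks(blocks, time_axis)
  if (!allow_missing && anyNA(values)) {
    abort("trait tensor has missing values; enable imputation explicitly")
  }
  dimnames(values) <- list(line_ids, trait_ids, time_axis)
  structure(
    list(values = values, line_ids = line_ids, trait_ids = trait_ids,
         time_axis = time_axis, blocks = blocks),
    class = "trait_tensor")
}

infer_blocks <- function(time_axis) {
  brk <- c(0, which(diff(time_axis) > 1), length(time_axis))
  lapply(seq_len(length(brk) - 1),
         function(i) seq(brk[i] + 1, brk[i + 1]))
}

validate_blocks <- function(blocks, time_axis) {
  idx <- unlist(blocks)
  if (!identical(sort(idx), seq_along(time_axis)))
    abort("blocks must partition the timepoint indices")
  if (!identical(idx, seq_along(time_axis)))
    abort("blocks must be consecutive and ordered")
  for (b in blocks) {
    if (length(b) > 1 && any(diff(time_axis[b]) != 1))
      abort("within a block, days must be consecutive")
  }
}

#' @export
print.trait_tensor <- function(x, ...) {
  cat(sprintf(
    "<trait_tensor> %d lines x %d traits x %d timepoints (days %d-%d, %d block%s)\n",
    length(x$line_ids), length(x$trait_ids), length(x$time_axis),
    min(x$time_axis), max(x$time_axis), length(x$blocks),
    if (length(x$blocks) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.trait_tensor <- function(x) dim(x$values)

#' Long-format view of a trait tensor
#'
#' @param x a [trait_tensor()].
#' @param ... unused.
#' @return A tibble with columns `line`, `trait`, `day`, `value`.
#' @method as_tibble trait_tensor
#' @export
as_tibble.trait_tensor <- function(x, ...) {
  d <- dim(x$values)
  tibble(
    line = rep(x$line_ids, times = d[2] * d[3]),
    trait = rep(rep(x$trait_ids, each = d[1]), times = d[3]),
    day = rep(x$time_axis, each = d[1] * d[2]),
    value = as.vector(x$values))
}

#' Read a trait tensor from a delimited file
#'
#' The long layout has columns `line`, `trait`, `day`, `value`; the wide
#' layout has columns `line`, `trait` followed by one column per day named
#' by the day. Lines and traits are ordered lexicographically; measurement
#' blocks are inferred from gaps in the day axis.
#'
#' @param path path to a CSV/TSV file.
#' @param layout `"long"` or `"wide"`.
#' @return A [trait_tensor()].
#' @export
read_trait_tensor <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("cannot read phenotype file '%s'", path))
  tab <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (layout == "wide") {
    tab <- tidyr::pivot_longer(tab, -c("line", "trait"),
                               names_to = "day", values_to = "value")
    tab$day <- as.integer(tab$day)
  }
  need <- c("line", "trait", "day", "value")
  if (!all(need %in% names(tab)))
    abort(sprintf("phenotype file must provide columns %s",
                  paste(need, collapse = ", ")))
  tensor_from_long(tab)
}

tensor_from_long <- function(tab) {
  tab$line <- as.character(tab$line)
  tab$trait <- as.character(tab$trait)
  tab$day <- as.integer(tab$day)
  lines <- sort(unique(tab$line))
  traits <- sort(unique(tab$trait))
  days <- sort(unique(tab$day))
  key <- paste(tab$line, tab$trait, tab$day, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf("duplicated (line, trait, day) combination(s), e.g. %s",
                  gsub("\r", "/", key[which(dup)[1]])))
  }
  full <- expand.grid(line = lines, trait = traits, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fkey <- paste(full$line, full$trait, full$day, sep = "\r")
  missing <- setdiff(fkey, key)
  if (length(missing)) {
    shown <- gsub("\r", "/", head(missing, 10))
    abort(sprintf("missing %d (line, trait, day) combination(s): %s%s",
                  length(missing), paste(shown, collapse = "; "),
                  if (length(missing) > 10) " ..." else ""))
  }
  arr <- array(NA_real_, dim = c(length(lines), length(traits), length(days)))
  i <- match(tab$line, lines); j <- match(tab$trait, traits)
  t_ <- match(tab$day, days)
  arr[cbind(i, j, t_)] <- tab$value
  trait_tensor(arr, lines, traits, days, allow_missing = TRUE) |>
    (\(x) { if (anyNA(x$values)) x else trait_tensor(x$values, x$line_ids, x$trait_ids, x$time_axis) })()
}

#' Fill missing tensor values with trait-by-day means
#'
#' Each `NA` is replaced by the mean over lines of the same trait at the
#' same day. A trait-day slice that is entirely missing cannot be imputed
#' and is an error.
#'
#' @param t a [trait_tensor()] possibly containing `NA`s.
#' @return A [trait_tensor()] without missing values.
#' @export
mean_impute_tensor <- function(t) {
  stopifnot(inherits(t, "trait_tensor"))
  vals <- t$values
  if (!anyNA(vals)) return(t)
  d <- dim(vals)
  for (j in seq_len(d[2])) for (tt in seq_len(d[3])) {
    col <- vals[, j, tt]
    if (anyNA(col)) {
      if (all(is.na(col))) {
        abort(sprintf("trait '%s' at day %d is entirely missing",
                      t$trait_ids[j], t$time_axis[tt]))
      }
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      vals[, j, tt] <- col
    }
  }
  trait_tensor(vals, t$line_ids, t$trait_ids, t$time_axis, t$blocks)
}
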