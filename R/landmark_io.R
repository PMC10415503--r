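#' Construct a raw suture trace
#'
#' A raw trace is the pipeline's input record: an ordered 2D polyline
#' digitised along a suture outline (anterior to posterior), plus specimen
#' metadata. Point order is anatomically meaningful and is preserved by all
#' I/O and resampling operations. Coordinates are in arbitrary planar units;
#' Procrustes scaling removes size downstream, so no physical calibration is
#' stored.
#'
#' @param specimen_id Character scalar identifying the specimen.
#' @param points Numeric matrix (or two-column data frame) of xy coordinates,
#'   at least two rows; consecutive duplicate points are forbidden.
#' @param age Age in years (nonnegative), or `NA` if unknown.
#' @param sex `"male"`, `"female"`, or `NA`.
#' @param session Integer label for repeated digitisations of the same
#'   specimen (default 1). Sessions are consumed only by the reliability
#'   analysis.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(specimen_id, points, age = NA_real_, sex = NA_character_,
                      session = 1L) {
  stopifnot(is.character(specimen_id), length(specimen_id) == 1L,
            nzchar(specimen_id))
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("trace points must have two columns (x, y)")
  storage.mode(points) <- "double"
  if (anyNA(points))
    stop("trace '", specimen_id, "' has missing coordinates")
  if (nrow(points) < 2L)
    stop("trace '", specimen_id, "' needs at least 2 points")
  dup <- rowSums(abs(diff(points))) == 0
  if (any(dup))
    stop("trace '", specimen_id, "' has consecutive duplicate points (at index ",
         which(dup)[1L] + 1L, ")")
  if (!is.na(age) && (!is.numeric(age) || age < 0))
    stop("age must be a nonnegative number of years")
  if (!is.na(sex) && !sex %in% c("male", "female"))
    stop("sex must be 'male', 'female', or NA")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(specimen_id = specimen_id, points = points,
                 age = as.numeric(age), sex = as.character(sex),
                 session = as.integer(session)),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat("<raw_trace> ", x$specimen_id, ": ", nrow(x$points), " points",
      if (!is.na(x$age)) paste0(", age ", x$age),
      if (!is.na(x$sex)) paste0(", ", x$sex),
      if (x$session != 1L) paste0(", session ", x$session), "\n", sep = "")
  invisible(x)
}

#' Construct a cohort of suture traces
#'
#' @param traces List of [raw_trace()] objects. `(specimen_id, session)`
#'   pairs must be unique.
#' @param group_labels Optional named integer vector mapping specimen ids to
#'   age-quartile groups 1..4; every labelled id must exist among the traces.
#' @return An object of class `suture_cohort`.
#' @export
suture_cohort <- function(traces, group_labels = NULL) {
  if (!is.list(traces) || !all(vapply(traces, inherits, logical(1), "raw_trace")))
    stop("traces must be a list of raw_trace objects")
  keys <- vapply(traces, function(tr) paste(tr$specimen_id, tr$session, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    d <- traces[[which(duplicated(keys))[1L]]]
    stop("duplicate specimen '", d$specimen_id, "' within session ", d$session)
  }
  if (!is.null(group_labels)) {
    ids <- unique(vapply(traces, `[[`, character(1), "specimen_id"))
    unknown <- setdiff(names(group_labels), ids)
    if (length(unknown))
      stop("group labels refer to unknown specimens: ",
           paste(unknown, collapse = ", "))
    group_labels <- stats::setNames(as.integer(group_labels), names(group_labels))
  }
  structure(list(traces = traces, group_labels = group_labels),
            class = "suture_cohort")
}

#' @export
print.suture_cohort <- function(x, ...) {
  ids <- cohort_ids(x)
  ses <- vapply(x$traces, `[[`, integer(1), "session")
  cat("<suture_cohort> ", length(unique(ids)), " specimens, ",
      length(x$traces), " traces",
      if (any(ses > 1L)) paste0(" (", length(unique(ses)), " sessions)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.suture_cohort <- function(x) length(x$traces)

#' Specimen ids of a cohort (one per trace, in storage order)
#' @param cohort A [suture_cohort()].
#' @export
cohort_ids <- function(cohort) {
  unname(vapply(cohort$traces, `[[`, character(1), "specimen_id"))
}

#' Per-specimen metadata of a cohort
#'
#' @param cohort A [suture_cohort()].
#' @return Data frame with one row per trace: specimen_id, session, age,
#'   sex, n_points, and group (NA where no label is present).
#' @export
cohort_metadata <- function(cohort) {
  df <- data.frame(
    specimen_id = cohort_ids(cohort),
    session = vapply(cohort$traces, `[[`, integer(1), "session"),
    age = vapply(cohort$traces, `[[`, numeric(1), "age"),
    sex = vapply(cohort$traces, `[[`, character(1), "sex"),
    n_points = vapply(cohort$traces, function(tr) nrow(tr$points), integer(1)),
    stringsAsFactors = FALSE)
  df$group <- if (is.null(cohort$group_labels)) NA_integer_ else
    unname(cohort$group_labels[df$specimen_id])
  df
}

#' Extract one session from a cohort
#' @param cohort A [suture_cohort()].
#' @param session Session label to keep.
#' @export
cohort_session <- function(cohort, session = 1L) {
  keep <- vapply(cohort$traces, function(tr) tr$session == session, logical(1))
  if (!any(keep)) stop("no traces with session ", session)
  suture_cohort(cohort$traces[keep], cohort$group_labels)
}

.parse_numeric <- function(v, what, rows) {
  out <- suppressWarnings(as.numeric(v))
  bad <- is.na(out) & !(is.na(v) | v == "")
  if (any(bad))
    stop("non-numeric ", what, " value '", v[bad][1L], "' at file row ",
         rows[bad][1L])
  out
}

.norm_sex <- function(s) {
  s <- tolower(trimws(as.character(s)))
  s[s %in% c("", "na")] <- NA_character_
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  s
}

#' Read suture traces from a delimited coordinate table
#'
#' Two dialects are supported. `"long"`: one row per landmark with columns
#' `specimen_id, point_index, x, y` and optional `age, sex, session`.
#' `"wide"`: one row per specimen with columns `x1,y1,...,xk,yk` (trailing
#' blank pairs allowed, so traces of different lengths can share a file) and
#' the same optional metadata columns.
#'
#' Traces digitised in image coordinates (y increasing downwards) should be
#' imported with `flip_y = TRUE`; all downstream geometry assumes a
#' mathematical y-up convention.
#'
#' @param path Path to a UTF-8 delimited text file.
#' @param dialect `"long"` or `"wide"`.
#' @param sep Field separator; comma by default, tab accepted.
#' @param flip_y Negate y at import (image-space traces).
#' @return A [suture_cohort()].
#' @export
read_trace_table <- function(path, dialect = c("long", "wide"), sep = ",",
                             flip_y = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          fileEncoding = "UTF-8")
  rows <- seq_len(nrow(df)) + 1L  # +1 for the header line
  traces <- if (dialect == "long") .traces_long(df, rows) else .traces_wide(df, rows)
  if (isTRUE(flip_y))
    traces <- lapply(traces, function(tr) { tr$points[, 2] <- -tr$points[, 2]; tr })
  suture_cohort(traces)
}

.meta_of <- function(sub) {
  list(age = if ("age" %in% names(sub))
         .parse_numeric(sub$age, "age", seq_len(nrow(sub)))[1L] else NA_real_,
       sex = if ("sex" %in% names(sub)) .norm_sex(sub$sex)[1L] else NA_character_,
       session = if ("session" %in% names(sub)) {
         s <- suppressWarnings(as.integer(sub$session[1L]))
         if (is.na(s)) 1L else s
       } else 1L)
}

.traces_long <- function(df, rows) {
  need <- c("specimen_id", "point_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long dialect requires columns: ", paste(miss, collapse = ", "))
  df$x <- .parse_numeric(df$x, "x", rows)
  df$y <- .parse_numeric(df$y, "y", rows)
  df$point_index <- .parse_numeric(df$point_index, "point_index", rows)
  ses <- if ("session" %in% names(df)) df$session else rep("1", nrow(df))
  key <- paste(df$specimen_id, ses, df$point_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (specimen_id, session, point_index) at file row ",
         rows[which(duplicated(key))[1L]])
  split_key <- paste(df$specimen_id, ses, sep = "\r")
  traces <- lapply(
    split(seq_len(nrow(df)), factor(split_key, levels = unique(split_key))),
    function(i) {
           sub <- df[i[order(df$point_index[i])], , drop = FALSE]
      m <- .meta_of(sub)
      raw_trace(sub$specimen_id[1L], cbind(sub$x, sub$y),
                age = m$age, sex = m$sex, session = m$session)
    })
  unname(traces)
}

.traces_wide <- function(df, rows) {
  if (!"specimen_id" %in% names(df))
    stop("wide dialect requires a specimen_id column")
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  k <- length(xcols)
  if (k == 0L || length(ycols) != k)
    stop("wide dialect requires paired coordinate columns x1,y1,...,xk,yk")
  xcols <- paste0("x", seq_len(k)); ycols <- paste0("y", seq_len(k))
  if (!all(c(xcols, ycols) %in% names(df)))
    stop("wide dialect coordinate columns must be numbered 1..k")
  lapply(seq_len(nrow(df)), function(i) {
    xs <- .parse_numeric(unlist(df[i, xcols]), "x", rep(rows[i], k))
    ys <- .parse_numeric(unlist(df[i, ycols]), "y", rep(rows[i], k))
    keep <- !(is.na(xs) & is.na(ys))
    if (any(is.na(xs[keep]) != is.na(ys[keep])))
      stop("unpaired coordinate at file row ", rows[i])
    m <- .meta_of(df[i, , drop = FALSE])
    raw_trace(df$specimen_id[i], cbind(xs[keep], ys[keep]),
              age = m$age, sex = m$sex, session = m$session)
  })
}

#' Read a TPS landmark file
#'
#' Parses the de-facto landmark exchange format of geometric morphometrics:
#' blocks starting `LM=k`, followed by k whitespace-separated coordinate
#' lines and an `ID=` record. `IMAGE=` and `SCALE=` records are tolerated and
#' ignored. Blocks without an `ID=` record get sequential ids.
#'
#' @param path Path to a TPS file.
#' @param flip_y Negate y at import (image-space traces).
#' @return A [suture_cohort()].
#' @export
read_tps <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in ", path)
  traces <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:(bounds[b + 1L] - 1L)]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 2L) stop("invalid LM= count in block ", b)
    body <- block[-1L]
    is_kv <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_kv]
    if (length(coord_lines) != k)
      stop("block ", b, ": LM=", k, " but ", length(coord_lines),
           " coordinate lines")
    xy <- t(vapply(strsplit(coord_lines, "\\s+"), function(p) {
      v <- suppressWarnings(as.numeric(p))
      if (length(v) < 2L || anyNA(v[1:2]))
        stop("block ", b, ": malformed coordinate line")
      v[1:2]
    }, numeric(2)))
    kv <- body[is_kv]
    getv <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), kv, ignore.case = TRUE, value = TRUE)
      if (length(hit)) sub("^[A-Za-z]+\\s*=\\s*", "", hit[1L]) else NA_character_
    }
    id <- getv("ID")
    if (is.na(id) || !nzchar(id)) id <- paste0("specimen_", b)
    if (isTRUE(flip_y)) xy[, 2] <- -xy[, 2]
    traces[[b]] <- raw_trace(id, xy)
  }
  suture_cohort(traces)
}

#' Write a cohort to a long-format coordinate table
#'
#' Coordinates are written at full double precision, so
#' `read_trace_table(write_trace_table(cohort))` reproduces the cohort
#' exactly. Metadata columns (age, sex, session) are included whenever any
#' trace carries them; absent values are left blank and round-trip to `NA`.
#'
#' @param cohort A nonempty [suture_cohort()].
#' @param path Output file path.
#' @param sep Field separator (comma default).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(cohort, path, sep = ",") {
  if (!inherits(cohort, "suture_cohort")) stop("cohort must be a suture_cohort")
  if (length(cohort$traces) == 0L) stop("cannot write an empty cohort")
  blocks <- lapply(cohort$traces, function(tr) {
    n <- nrow(tr$points)
    data.frame(specimen_id = rep(tr$specimen_id, n),
               session = rep(tr$session, n),
               point_index = seq_len(n),
               x = sprintf("%.17g", tr$points[, 1]),
               y = sprintf("%.17g", tr$points[, 2]),
               age = rep(if (is.na(tr$age)) "" else sprintf("%.17g", tr$age), n),
               sex = rep(if (is.na(tr$sex)) "" else tr$sex, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  if (all(out$age == "")) out$age <- NULL
  if (all(out$sex == "")) out$sex <- NULL
  if (all(out$session == 1L)) out$session <- NULL
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to '", path, "': ", conditionMessage(ok))
  invisible(path)
}
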