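# File formats: TPS landmark files, labeled-coordinate outline CSV,
# measurement CSV, and YAML/JSON run configuration.
#
# TPS dialect used here: one record per specimen with
#   LM=<2 or 4>           named landmarks: tip, articulation base
#                         (then handle tip, handle base when present)
#   CURVES=2 / POINTS=n   curve 1 = inner edge, curve 2 = outer edge,
#                         both ordered tip -> base
#   ID=<specimen id>
#   SCALE=<um per unit>   coordinates are multiplied by SCALE on read
# The straight shaft section is not representable in TPS; readers fall back
# to the proximal-40% default of hook_outline().

#' Write hook outlines to a TPS landmark file
#'
#' @param outlines List of [hook_outline()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landmarks_tps <- function(outlines, path) {
  stopifnot(is.list(outlines))
  fmt <- function(m) sprintf("%.10g %.10g", m[, 1], m[, 2])
  con <- file(path, "w")
  on.exit(close(con))
  for (o in outlines) {
    stopifnot(inherits(o, "hook_outline"))
    lms <- rbind(o$tip, o$articulation_base)
    if (!is.null(o$handle)) lms <- rbind(lms, o$handle)
    writeLines(c(sprintf("LM=%d", nrow(lms)), fmt(lms),
                 "CURVES=2",
                 sprintf("POINTS=%d", nrow(o$inner_edge)), fmt(o$inner_edge),
                 sprintf("POINTS=%d", nrow(o$outer_edge)), fmt(o$outer_edge),
                 sprintf("ID=%s", o$id), "SCALE=1.0"), con)
  }
  invisible(path)
}

#' Read hook outlines from a TPS landmark file
#'
#' Coordinates are multiplied by the record's `SCALE=` value (default 1) so
#' outlines are returned in micrometres. A record must carry 2 or 4
#' landmarks (tip, base, optional handle tip/base) and exactly two curves
#' (inner then outer edge, ordered tip to base). Malformed or truncated
#' records raise a parse error naming the record; nothing partial is
#' returned.
#'
#' @param path TPS file path.
#' @return List of [hook_outline()] objects.
#' @export
read_landmarks_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines)
  if (!length(starts)) stop("no TPS records (missing LM=) in ", path,
                            call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[bounds[r]:(bounds[r + 1L] - 1L)]
    id <- sub("^ID=", "", grep("^ID=", rec, value = TRUE)[1])
    fail <- function(msg) {
      stop(sprintf("TPS record %d ('%s'): %s", r,
                   if (is.na(id)) "?" else id, msg), call. = FALSE)
    }
    read_xy <- function(block) {
      xy <- strsplit(block, "\\s+")
      if (any(lengths(xy) != 2)) fail("malformed coordinate line")
      m <- matrix(as.numeric(unlist(xy)), ncol = 2, byrow = TRUE)
      if (any(is.na(m))) fail("non-numeric coordinate")
      m
    }
    n_lm <- as.integer(sub("^LM=", "", rec[1]))
    if (is.na(n_lm) || !(n_lm %in% c(2L, 4L))) {
      fail("LM= must be 2 (tip, base) or 4 (plus handle tip/base)")
    }
    if (length(rec) < 1 + n_lm) fail("truncated landmark block")
    lms <- read_xy(rec[2:(1 + n_lm)])
    i <- 2 + n_lm
    if (i > length(rec) || rec[i] != "CURVES=2") {
      fail("expected CURVES=2 (inner and outer edge)")
    }
    curves <- list()
    i <- i + 1
    for (cc in 1:2) {
      if (i > length(rec) || !grepl("^POINTS=", rec[i])) {
        fail("expected POINTS= header")
      }
      np <- as.integer(sub("^POINTS=", "", rec[i]))
      if (is.na(np) || np < 2) fail("bad POINTS= count")
      if (i + np > length(rec)) fail("truncated curve block")
      curves[[cc]] <- read_xy(rec[(i + 1):(i + np)])
      i <- i + np + 1
    }
    scale_line <- grep("^SCALE=", rec, value = TRUE)
    scl <- if (length(scale_line)) as.numeric(sub("^SCALE=", "",
                                                  scale_line[1])) else 1
    if (is.na(scl) || scl <= 0) fail("bad SCALE= value")
    if (is.na(id)) fail("missing ID= field")
    out[[r]] <- hook_outline(
      inner_edge = curves[[1]], outer_edge = curves[[2]],
      articulation_base = lms[2, ],
      handle = if (n_lm == 4L) lms[3:4, , drop = FALSE] else NULL,
      units_scale = scl, id = id)
  }
  out
}

#' Write / read hook outlines as labeled-coordinate CSV
#'
#' Long-format CSV with columns `specimen_id`, `edge_label` (one of `inner`,
#' `outer`, `handle`, `tip`, `base`), `vertex_index`, `x`, `y`. The `tip` and
#' `base` rows carry the named landmarks; coordinates are micrometres.
#'
#' @param outlines List of [hook_outline()] objects.
#' @param path CSV path.
#' @return `path` (writer) or a list of outlines (reader).
#' @export
write_outline_csv <- function(outlines, path) {
  rows <- lapply(outlines, function(o) {
    stopifnot(inherits(o, "hook_outline"))
    blk <- function(label, m) {
      data.frame(specimen_id = o$id, edge_label = label,
                 vertex_index = seq_len(nrow(m)), x = m[, 1], y = m[, 2],
                 stringsAsFactors = FALSE)
    }
    out <- rbind(blk("tip", matrix(o$tip, 1)),
                 blk("base", matrix(o$articulation_base, 1)),
                 blk("inner", o$inner_edge), blk("outer", o$outer_edge))
    if (!is.null(o$handle)) out <- rbind(out, blk("handle", o$handle))
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "edge_label", "vertex_index", "x", "y")
  if (!all(need %in% names(d))) {
    stop("outline CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(d, d$specimen_id), function(sub) {
    sub <- sub[order(sub$edge_label, sub$vertex_index), ]
    get <- function(label, required = TRUE, min_rows = 1) {
      m <- as.matrix(sub[sub$edge_label == label, c("x", "y")])
      if (nrow(m) < min_rows) {
        if (required) {
          stop(sprintf("specimen '%s': missing or short '%s' block",
                       sub$specimen_id[1], label), call. = FALSE)
        }
        return(NULL)
      }
      m
    }
    hook_outline(inner_edge = get("inner", min_rows = 2),
                 outer_edge = get("outer", min_rows = 2),
                 articulation_base = get("base")[1, ],
                 handle = get("handle", required = FALSE, min_rows = 2),
                 id = sub$specimen_id[1])
  })
}

#' Write / read a measurement table CSV
#'
#' Standard dialect: comma-separated, `.` decimal, UTF-8, mandatory header
#' `specimen_id, species`, then the 14 variable names. Optional `#` comment
#' lines (run provenance) precede the header and are skipped on read.
#'
#' @param data Measurement data.frame.
#' @param path CSV path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_measurements_csv <- function(data, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("specimen_id", "species") %in% names(d))) {
    stop("measurement CSV must have 'specimen_id' and 'species' columns",
         call. = FALSE)
  }
  d
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' The configuration mirrors the arguments of [run_pipeline()]: exactly one
#' of an `input` block (paths to measurement or landmark files) or a
#' `simulate` block (n, seed, truncate, optional species overrides), plus
#' optional `geometry` and `stats` blocks and an `output_dir`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return The configuration list, validated.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim) {
    stop("config must have exactly one of 'input' or 'simulate'",
         call. = FALSE)
  }
  alpha <- cfg$stats$alpha %||% 0.05
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)",
                                      call. = FALSE)
  cfg
}
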