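#' Read and write decision-matrix CSV files
#'
#' The on-disk dialect is UTF-8 comma-separated text. `#`-prefixed
#' directive rows come before the data header:
#'
#' ```
#' #aim,max,max,min
#' #weight,VH,H,0.6
#' #pf,gaussian,gaussian,gaussian
#' #pf_s,,0.2,          (optional explicit thresholds; also #pf_q, #pf_p)
#' alternative,acc,prec,time
#' a,94.1|H,90|H,429|M
#' ```
#'
#' Cells are a bare number (`94.1`), a bare term (`H`), or both
#' (`94.1|H`). Lines starting `"# "` are comments; a `# seed: <int>`
#' comment (written for simulated matrices) is restored as the matrix's
#' seed attribute. Attached banding tables are stored one criterion per
#' row as `#band,<criterion>,<lower>:<upper>:<term>,...`, so writing and
#' re-reading a matrix is an exact round-trip.
#'
#' @param path File path.
#' @param scale A [linguistic_scale()] used to interpret terms.
#' @param banding Optional banding to attach, as in [decision_matrix()].
#' @return `read_decision_csv()` returns a [decision_matrix()];
#'   `write_decision_csv()` returns `path` invisibly.
#' @export
read_decision_csv <- function(path, scale = default_scale(), banding = NULL) {
  if (!file.exists(path)) abort_input(paste0("File not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[str_trim(lines) != ""]
  directives <- list()
  band_rows <- list()
  seed <- NULL
  data_lines <- character()
  known <- c("aim", "weight", "pf", "pf_q", "pf_p", "pf_s", "band")
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (str_starts(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*seed:\\s*(-?[0-9]+)\\s*$", line))[[1L]]
      if (length(m) == 2L) { seed <- as.integer(m[2L]); next }
      if (str_starts(line, "# ")) next # free comment
      # str_split keeps trailing empty fields (e.g. "#pf_q,0.1,")
      fields <- str_trim(stringr::str_split(sub("^#", "", line), ",")[[1L]])
      key <- fields[1L]
      if (!key %in% known) {
        abort_input(paste0("Line ", i, " of '", path, "': unknown directive '#",
                           key, "'. Known directives: ",
                           paste(paste0("#", known), collapse = ", "), "."))
      }
      if (key == "band") {
        if (length(fields) < 3L) {
          abort_input(paste0("Line ", i, " of '", path,
                             "': #band needs a criterion name and >= 1 lower:upper:term entry."))
        }
        band_rows[[fields[2L]]] <- parse_band_entries(fields[-(1:2)], path, i)
        next
      }
      directives[[key]] <- fields[-1L]
    } else {
      data_lines <- c(data_lines, line)
    }
  }
  if (length(data_lines) < 3L) {
    abort_input(paste0("'", path, "' needs a header row and at least 2 alternative rows."))
  }
  df <- tryCatch(
    read.csv(text = paste(data_lines, collapse = "\n"), check.names = FALSE,
             colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) abort_input(paste0("Malformed CSV in '", path, "': ",
                                           conditionMessage(e))))
  k <- ncol(df) - 1L
  if (is.null(directives$aim)) abort_input(paste0("'", path, "' is missing the #aim directive row."))
  if (is.null(directives$weight)) abort_input(paste0("'", path, "' is missing the #weight directive row."))
  for (key in names(directives)) {
    if (length(directives[[key]]) != k) {
      abort_input(paste0("Directive #", key, " in '", path, "' has ",
                         length(directives[[key]]), " entries but there are ",
                         k, " criteria."))
    }
  }
  num_or_na <- function(x) {
    x[x == ""] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  dm <- decision_matrix(
    df,
    aim = directives$aim,
    weight = directives$weight,
    pf = directives$pf %||% "gaussian",
    q = num_or_na(directives$pf_q %||% rep(NA_character_, k)),
    p = num_or_na(directives$pf_p %||% rep(NA_character_, k)),
    s = num_or_na(directives$pf_s %||% rep(NA_character_, k)),
    scale = scale,
    banding = banding %||% (if (length(band_rows)) band_rows else NULL)
  )
  if (!is.null(seed)) attr(dm, "seed") <- seed
  dm
}

parse_band_entries <- function(entries, path, line_no) {
  parts <- str_split_fixed(entries, ":", 3L)
  if (any(parts == "")) {
    abort_input(paste0("Line ", line_no, " of '", path,
                       "': #band entries must look like lower:upper:term."))
  }
  bands(as.numeric(parts[, 1L]), as.numeric(parts[, 2L]), parts[, 3L])
}

#' @param dm A [decision_matrix()].
#' @rdname read_decision_csv
#' @export
write_decision_csv <- function(dm, path) {
  stopifnot(inherits(dm, "decision_matrix"))
  cr <- dm$criteria
  fmt_opt <- function(x) ifelse(is.na(x), "", fmt_num(x))
  lines <- character()
  if (!is.null(attr(dm, "seed"))) {
    lines <- c(lines, paste0("#seed: ", attr(dm, "seed")))
  }
  lines <- c(lines,
             paste0("#aim,", paste(cr$aim, collapse = ",")),
             paste0("#weight,", paste(ifelse(is.na(cr$weight_term),
                                             fmt_num(cr$weight_crisp),
                                             cr$weight_term), collapse = ",")),
             paste0("#pf,", paste(cr$pf, collapse = ",")))
  for (key in c("q", "p", "s")) {
    if (any(!is.na(cr[[key]]))) {
      lines <- c(lines, paste0("#pf_", key, ",", paste(fmt_opt(cr[[key]]), collapse = ",")))
    }
  }
  for (nm in names(dm$banding)) {
    b <- dm$banding[[nm]]
    lines <- c(lines, paste0("#band,", nm, ",",
                             paste(paste0(fmt_num(b$lower), ":", fmt_num(b$upper),
                                          ":", b$term), collapse = ",")))
  }
  lines <- c(lines, paste0("alternative,", paste(cr$name, collapse = ",")))
  for (i in seq_len(n_alternatives(dm))) {
    lines <- c(lines, paste0(dm$alternatives[i], ",",
                             paste(format_cell(dm$raw[i, ], dm$terms[i, ]),
                                   collapse = ",")))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
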