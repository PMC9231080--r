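#' Write a time trace to a delimited text file
#'
#' Format: comment-prefixed header lines (`# label=`, `# n_averaged=`,
#' `# tablet=`, `# time_unit=ps`) followed by two whitespace-separated
#' columns `time amplitude`.
#'
#' @param trace A `thz_trace`.
#' @param path Output file path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "thz_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label=", trace$label),
               paste0("# n_averaged=", trace$n_averaged),
               paste0("# tablet=", trace$tablet_id),
               "# time_unit=ps"), con)
  utils::write.table(data.frame(time = trace$t, amplitude = trace$amplitude),
                     con, row.names = FALSE, col.names = FALSE)
}

#' Read a time trace written by [write_trace()]
#' @param path Input file path.
#' @return A `thz_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1]) else default
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  time_trace(dat[[1]], dat[[2]],
             n_averaged = as.integer(get("n_averaged", "1")),
             label = get("label", "reference"),
             tablet_id = as.integer(get("tablet", "0")))
}

#' Write optical constants to a delimited text file
#'
#' Columns `f_THz n alpha_per_mm` with header comments carrying the slab
#' thickness and provenance fields.
#'
#' @param oc A `thz_optical`.
#' @param path Output file path.
#' @param provenance Optional named character vector echoed into the
#'   header.
#' @export
write_optical_constants <- function(oc, path, provenance = NULL) {
  stopifnot(inherits(oc, "thz_optical"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# d_mm=", oc$d), con)
  for (k in names(provenance))
    writeLines(paste0("# ", k, "=", provenance[[k]]), con)
  writeLines("# f_THz n alpha_per_mm", con)
  utils::write.table(data.frame(oc$f, oc$n, oc$alpha), con,
                     row.names = FALSE, col.names = FALSE)
}

#' Read optical constants written by [write_optical_constants()]
#' @param path Input file path.
#' @return A `thz_optical`.
#' @export
read_optical_constants <- function(path) {
  lines <- readLines(path)
  d <- as.numeric(sub("^# d_mm=", "",
                      grep("^# d_mm=", lines, value = TRUE)[1]))
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  optical_constants(dat[[1]], dat[[2]], dat[[3]], d)
}

#' Save / load a campaign or feature container
#'
#' Binary single-file container (RDS) for simulated campaigns, feature
#' sets and trained models produced at run time.
#'
#' @param object Object to store.
#' @param path File path (conventionally `.rds`).
#' @export
save_container <- function(object, path) saveRDS(object, path)

#' @rdname save_container
#' @export
load_container <- function(path) readRDS(path)

#' Write an evaluation report as JSON
#'
#' @param report A `thz_eval` (or a list of them).
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  to_plain <- function(ev) {
    list(split = ev$split_tag, n_items = ev$n_items,
         accuracy = ev$accuracy,
         per_class = as.list(ev$per_class),
         confusion = unclass(ev$confusion),
         throughput_fps = ev$throughput_fps)
  }
  x <- if (inherits(report, "thz_eval")) to_plain(report)
       else lapply(report, function(e)
         if (inherits(e, "thz_eval")) to_plain(e) else e)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
}

#' Write a confusion matrix as delimited text with class-name header
#' @param cm A `thz_confusion`.
#' @param path Output path.
#' @export
write_confusion <- function(cm, path) {
  utils::write.table(as.data.frame(unclass(cm)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
}
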