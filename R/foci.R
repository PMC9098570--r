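#' A single coordinate-based morphometry experiment
#'
#' Holds the reported alteration peaks ("foci", MNI mm) and the clinical
#' sample size of one voxel-based-morphometry experiment.
#'
#' @param id character scalar, unique within an [experiment_set()].
#' @param n_subjects positive integer count of clinical subjects.
#' @param foci numeric n x 3 matrix (or length-3 vector) of MNI mm peaks;
#'   must be non-empty and finite.
#' @param meta optional named list of free-text tags (diagnosis, contrast).
#' @return An object of class `foci_experiment`.
#' @export
foci_experiment <- function(id, n_subjects, foci, meta = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("n_subjects must be a positive integer (experiment ", id, ")")
  foci <- to_points_matrix(foci)
  if (nrow(foci) < 1L) stop("foci list must be non-empty (experiment ", id, ")")
  structure(list(id = id, n_subjects = n_subjects, foci = foci, meta = meta),
            class = "foci_experiment")
}

#' A set of morphometry experiments
#'
#' The meta-analytic unit of observation: at least two experiments with
#' unique ids (co-alteration probabilities need two or more observations).
#'
#' @param experiments list of [foci_experiment()] objects.
#' @return An object of class `experiment_set`.
#' @export
experiment_set <- function(experiments) {
  stopifnot(is.list(experiments), length(experiments) >= 2L)
  ok <- vapply(experiments, inherits, logical(1), "foci_experiment")
  if (!all(ok)) stop("all elements must be foci_experiment objects")
  ids <- vapply(experiments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("experiment ids must be unique: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(experiments) <- ids
  structure(list(experiments = experiments), class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  nf <- sum(vapply(x$experiments, function(e) nrow(e$foci), integer(1)))
  cat("<experiment_set> ", length(x$experiments), " experiments, ",
      nf, " foci\n", sep = "")
  invisible(x)
}

#' @export
length.experiment_set <- function(x) length(x$experiments)

experiment_ids <- function(set) names(set$experiments)

#' Read a Sleuth-style foci text file
#'
#' Dialect: an optional `// Reference=MNI` declaration; experiments are
#' blocks separated by blank lines; each block starts with `//` comment
#' header lines carrying a study label and a `Subjects=N` field, followed by
#' one whitespace-separated `x y z` millimetre coordinate per line.
#'
#' @param path path to the text file.
#' @return An [experiment_set()].
#' @export
read_foci_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  exps <- list()
  cur_label <- NULL; cur_n <- NA_integer_; cur_foci <- NULL; cur_meta <- character()
  flush_block <- function() {
    if (is.null(cur_foci) && is.null(cur_label)) return(invisible())
    if (is.null(cur_foci))
      stop("experiment block '", cur_label, "' has no coordinate lines")
    if (is.na(cur_n))
      stop("missing 'Subjects=N' header for experiment block '",
           if (is.null(cur_label)) length(exps) + 1 else cur_label, "'")
    id <- if (is.null(cur_label)) sprintf("experiment_%03d", length(exps) + 1)
          else cur_label
    meta <- if (length(cur_meta)) list(header = cur_meta) else list()
    exps[[length(exps) + 1L]] <<- foci_experiment(id, cur_n,
                                                  do.call(rbind, cur_foci), meta)
    cur_label <<- NULL; cur_n <<- NA_integer_; cur_foci <<- NULL
    cur_meta <<- character()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { flush_block(); next }
    if (startsWith(ln, "//")) {
      body <- trimws(sub("^//+", "", ln))
      m <- regmatches(body, regexec("^Reference[[:space:]]*=[[:space:]]*([^[:space:]]+)",
                                    body, ignore.case = TRUE))[[1]]
      if (length(m)) {
        if (toupper(m[2]) != "MNI")
          stop("unsupported reference space '", m[2], "' (line ", i,
               "); only MNI is accepted")
        next
      }
      m <- regmatches(body, regexec("Subjects[[:space:]]*=[[:space:]]*([[:digit:]]+)",
                                    body, ignore.case = TRUE))[[1]]
      if (length(m)) { cur_n <- as.integer(m[2]); next }
      if (is.null(cur_label) && nzchar(body)) cur_label <- body
      else cur_meta <- c(cur_meta, body)
      next
    }
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    xyz <- suppressWarnings(as.numeric(parts))
    if (length(xyz) != 3L || anyNA(xyz))
      stop("malformed coordinate line ", i, ": '", lines[i], "'")
    cur_foci[[length(cur_foci) + 1L]] <- xyz
  }
  flush_block()
  experiment_set(exps)
}

#' Write an experiment set in the foci text dialect
#'
#' @param set an [experiment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_foci_text <- function(set, path) {
  stopifnot(inherits(set, "experiment_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("// Reference=MNI", con)
  writeLines("", con)
  for (e in set$experiments) {
    writeLines(paste0("// ", e$id), con)
    writeLines(paste0("// Subjects=", e$n_subjects), con)
    if (length(e$meta$header))
      writeLines(paste0("// ", e$meta$header), con)
    writeLines(apply(e$foci, 1, function(p)
      paste(formatC(p, format = "fg", digits = 15), collapse = "\t")), con)
    writeLines("", con)
  }
  invisible(path)
}
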