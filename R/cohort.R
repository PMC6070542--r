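#' Assemble a test-retest cohort of connectivity matrices
#'
#' A cohort holds one symmetric connectivity-probability matrix per subject
#' and session (scan), plus node labels. Matrices must share dimensions,
#' be symmetric with a zero diagonal, and have entries in \[0, 1\]; every
#' subject must have the same set of sessions.
#'
#' @param scans Nested list: `scans[[subject_id]][[session_id]]` is an
#'   n x n numeric matrix.
#' @param node_labels Character vector of node names; defaults to
#'   `n001, n002, ...`.
#' @return An object of class `connrep_cohort` with elements `scans`,
#'   `node_labels`, `n_nodes`, `subjects`, `sessions`.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 0.5
#' coh <- cohort(list(s1 = list(`1` = m, `2` = m),
#'                    s2 = list(`1` = m, `2` = m)))
#' @export
cohort <- function(scans, node_labels = NULL) {
  if (!is.list(scans) || length(scans) < 1L)
    stop("'scans' must be a non-empty nested list", call. = FALSE)
  subjects <- names(scans)
  if (is.null(subjects) || any(subjects == ""))
    stop("'scans' must be named by subject id", call. = FALSE)
  sessions <- names(scans[[1]])
  if (is.null(sessions) || any(sessions == ""))
    stop("scans of each subject must be named by session id", call. = FALSE)
  n <- nrow(scans[[1]][[1]])
  if (is.null(node_labels)) node_labels <- sprintf("n%03d", seq_len(n))
  if (length(node_labels) != n)
    stop("'node_labels' length does not match matrix dimension",
         call. = FALSE)
  for (s in subjects) {
    if (!identical(sort(names(scans[[s]])), sort(sessions)))
      stop(sprintf("subject '%s' does not have the same sessions as others",
                   s), call. = FALSE)
    for (r in sessions) {
      m <- scans[[s]][[r]]
      assert_connectivity_matrix(m, sprintf("scan %s/%s", s, r))
      if (nrow(m) != n)
        stop(sprintf("scan %s/%s has %d nodes, expected %d",
                     s, r, nrow(m), n), call. = FALSE)
      dimnames(scans[[s]][[r]]) <- list(node_labels, node_labels)
    }
  }
  structure(list(scans = scans, node_labels = node_labels, n_nodes = n,
                 subjects = subjects, sessions = sessions),
            class = "connrep_cohort")
}

#' @export
print.connrep_cohort <- function(x, ...) {
  cat(sprintf("connrep cohort: %d subjects x %d sessions, %d nodes (%d edges)\n",
              length(x$subjects), length(x$sessions), x$n_nodes,
              x$n_nodes * (x$n_nodes - 1) / 2))
  invisible(x)
}

# Flat list of all scan matrices (session order nested within subject).
cohort_scan_list <- function(cohort, sessions = cohort$sessions) {
  out <- list()
  for (s in cohort$subjects)
    for (r in sessions)
      out[[paste(s, r, sep = "/")]] <- cohort$scans[[s]][[r]]
  out
}

# subjects x sessions x edges array of upper-triangle values; the layout
# consumed by the reproducibility module.
cohort_edge_array <- function(cohort) {
  S <- length(cohort$subjects); K <- length(cohort$sessions)
  E <- cohort$n_nodes * (cohort$n_nodes - 1) / 2
  a <- array(NA_real_, c(S, K, E),
             dimnames = list(cohort$subjects, cohort$sessions, NULL))
  for (si in seq_len(S))
    for (ki in seq_len(K))
      a[si, ki, ] <- upper_tri_values(
        cohort$scans[[cohort$subjects[si]]][[cohort$sessions[ki]]])
  a
}

#' Write a cohort to a directory of delimited text matrices
#'
#' Layout: `dir/sub-<id>/ses-<id>.tsv`, one square tab-separated matrix per
#' scan with a header row of node labels, plus `dir/nodes.tsv`.
#'
#' @param cohort A [cohort()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "connrep_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("label", cohort$node_labels), file.path(dir, "nodes.tsv"))
  for (s in cohort$subjects) {
    sdir <- file.path(dir, paste0("sub-", s))
    dir.create(sdir, showWarnings = FALSE)
    for (r in cohort$sessions)
      write_matrix_tsv(cohort$scans[[s]][[r]],
                       file.path(sdir, paste0("ses-", r, ".tsv")))
  }
  invisible(dir)
}

#' Read a cohort from a directory of delimited text matrices
#'
#' Inverse of [write_cohort()]: expects `sub-*/ses-*.tsv` (or `.csv`)
#' matrices and an optional `nodes.tsv` label file. All matrices are
#' validated against the cohort invariants.
#'
#' @param dir Cohort directory.
#' @return A [cohort()] object.
#' @export
read_cohort <- function(dir) {
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  subdirs <- subdirs[grepl("^sub-", basename(subdirs))]
  if (length(subdirs) == 0L)
    stop(sprintf("no 'sub-*' directories found under '%s'", dir),
         call. = FALSE)
  labels <- NULL
  nodefile <- file.path(dir, "nodes.tsv")
  if (file.exists(nodefile)) {
    lab <- readLines(nodefile)
    labels <- lab[-1]
  }
  scans <- list()
  for (sd in subdirs) {
    sid <- sub("^sub-", "", basename(sd))
    files <- sort(list.files(sd, pattern = "^ses-.*\\.(tsv|csv)$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop(sprintf("no 'ses-*' matrices under '%s'", sd), call. = FALSE)
    scans[[sid]] <- list()
    for (f in files) {
      rid <- sub("^ses-", "", tools::file_path_sans_ext(basename(f)))
      scans[[sid]][[rid]] <- read_matrix_file(f)
    }
  }
  cohort(scans, node_labels = labels)
}
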