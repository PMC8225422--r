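# Delimited-text exports of a simulation trace.  Everything is plain text
# at a fixed precision of 9 significant digits so cross-run diffs are
# meaningful; large raw traces are re-derivable from config + seed.

.fmt <- function(x) formatC(x, digits = 9, format = "g")

#' Export a trace to delimited text files
#'
#' Writes, into `dir`:
#' \describe{
#'   \item{`states.tsv`}{`time` plus one `V<i>` column per neuron (mV).}
#'   \item{`degrees.tsv`}{`time` plus one degree column per neuron.}
#'   \item{`sync.tsv`}{The whole-network [sync_series()].}
#'   \item{`snapshots.edges`}{One `t_start t_end i j` line per active edge
#'     per window (0-based indices); windows without edges contribute
#'     nothing beyond the header.}
#'   \item{`stability.tsv`}{The [window_report()] table.}
#'   \item{`manifest.yaml`}{Config snapshot, seed and output inventory.}
#' }
#'
#' @param trace A [run_simulation()] trace.
#' @param dir Output directory (created if needed).
#' @param what Subset of `c("states", "degrees", "sync", "snapshots",
#'   "stability")` to write.
#' @return Named character vector of the files written, invisibly.
#' @export
export_trace <- function(trace, dir,
                         what = c("states", "degrees", "sync", "snapshots",
                                  "stability")) {
  what <- match.arg(what, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  N <- trace$config$N

  if ("states" %in% what) {
    f <- file.path(dir, "states.tsv")
    df <- data.frame(time = .fmt(trace$times))
    for (i in seq_len(N)) df[[paste0("V", i)]] <- .fmt(trace$V[, i])
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["states"] <- f
  }
  if ("degrees" %in% what) {
    f <- file.path(dir, "degrees.tsv")
    deg <- degree_series(trace)
    df <- data.frame(time = .fmt(trace$times))
    for (i in seq_len(N)) df[[paste0("k", i)]] <- deg[, i]
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["degrees"] <- f
  }
  if ("sync" %in% what) {
    f <- file.path(dir, "sync.tsv")
    ss <- sync_series(trace)
    ss$time <- .fmt(ss$time); ss$mu <- .fmt(ss$mu)
    ss$sigma <- .fmt(ss$sigma); ss$S <- .fmt(ss$S)
    utils::write.table(ss, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["sync"] <- f
  }
  if ("snapshots" %in% what) {
    f <- file.path(dir, "snapshots.edges")
    con <- file(f, "w")
    writeLines("# t_start t_end i j", con)
    for (s in trace$snapshots) {
      if (nrow(s$edges))
        writeLines(sprintf("%s %s %d %d", .fmt(s$t_start), .fmt(s$t_end),
                           s$edges[, 1] - 1L, s$edges[, 2] - 1L), con)
    }
    close(con)
    files["snapshots"] <- f
  }
  if ("stability" %in% what) {
    f <- file.path(dir, "stability.tsv")
    wr <- window_report(trace)
    wr$t_start <- .fmt(wr$t_start); wr$t_end <- .fmt(wr$t_end)
    wr$lambda2_max <- .fmt(wr$lambda2_max); wr$d_bar <- .fmt(wr$d_bar)
    utils::write.table(wr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["stability"] <- f
  }

  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    package_version = as.character(utils::packageVersion("plastinet")),
    seed = trace$config$seed,
    N = N, t_end = trace$config$t_end, t_couple = trace$config$t_couple,
    files = as.list(basename(files)),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), manifest)
  files["manifest"] <- manifest
  invisible(files)
}

#' Read a snapshot edge-list file
#'
#' Parses the `snapshots.edges` format written by [export_trace()].
#'
#' @param path Path to the edge-list file.
#' @return A data frame with columns `t_start`, `t_end`, `i`, `j`
#'   (0-based node indices); zero rows if no window had edges.
#' @export
read_snapshot_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      i = integer(0), j = integer(0)))
  parts <- do.call(rbind, strsplit(lines, "\\s+"))
  data.frame(t_start = as.numeric(parts[, 1]),
             t_end = as.numeric(parts[, 2]),
             i = as.integer(parts[, 3]), j = as.integer(parts[, 4]))
}
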