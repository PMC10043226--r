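#' Write / read a connectivity matrix as delimited text
#'
#' The full weight matrix, tab-separated, no row or column names.  Focal
#' indices and the global scale travel in a YAML sidecar
#' (`<path>.meta.yml`).
#'
#' @param cm an `epi_connectivity`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "epi_connectivity"))
  write.table(cm$weights, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  yaml::write_yaml(list(n = cm$n, focal_indices = as.integer(cm$focal_indices),
                        global_scale = cm$global_scale),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  w <- as.matrix(read.table(path, sep = "\t"))
  dimnames(w) <- NULL
  meta_path <- paste0(path, ".meta.yml")
  focal <- integer(0); scale <- 1.0
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    focal <- as.integer(meta$focal_indices)
    scale <- meta$global_scale
  }
  connectivity_matrix(w, focal_indices = focal, global_scale = scale)
}

#' Write / read a connectivity matrix as a weighted edge list
#'
#' Three tab-separated columns `i j w` with 0-based node indices; each
#' undirected edge appears once with `i < j`.  Zero-weight pairs are
#' omitted.
#'
#' @param cm an `epi_connectivity`.
#' @param path output file.
#' @param n node count (needed on read since isolated nodes leave no
#'   rows).
#' @return `path` invisibly (write); an `epi_connectivity` (read).
#' @export
write_edgelist <- function(cm, path) {
  stopifnot(inherits(cm, "epi_connectivity"))
  ut <- which(upper.tri(cm$weights) & cm$weights > 0, arr.ind = TRUE)
  df <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                   w = cm$weights[ut])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, n) {
  df <- read.table(path, sep = "\t", header = TRUE)
  w <- matrix(0, n, n)
  w[cbind(df$i + 1L, df$j + 1L)] <- df$w
  w <- w + t(w)
  connectivity_matrix(w)
}

#' Write / read an excitability profile
#'
#' Two tab-separated columns (`node`, `x0`, 0-based node ids) preceded by
#' comment lines recording the distribution parameters and seed used to
#' draw it.
#'
#' @param profile an `epi_excitability`.
#' @param path output file.
#' @param seed the seed the profile was drawn with (recorded in the
#'   header).
#' @return `path` invisibly (write); an `epi_excitability` (read).
#' @export
write_x0_profile <- function(profile, path, seed = NA) {
  stopifnot(inherits(profile, "epi_excitability"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mu=%g sigma=%g x0_nonfocal=%g seed=%s focal=%s",
                     profile$mu, profile$sigma, profile$x0_nonfocal,
                     as.character(seed),
                     paste(profile$focal_indices - 1L, collapse = ",")),
             con)
  writeLines("node\tx0", con)
  writeLines(sprintf("%d\t%.17g", seq_along(profile$x0_values) - 1L,
                     profile$x0_values), con)
  invisible(path)
}

#' @rdname write_x0_profile
#' @export
read_x0_profile <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z_0-9]+=[^ ]+", header))[[1]]
  vals <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  focal <- if (nzchar(vals[["focal"]]))
    as.integer(strsplit(vals[["focal"]], ",")[[1]]) + 1L else integer(0)
  structure(list(x0_values = df$x0, focal_indices = focal,
                 mu = as.numeric(vals[["mu"]]),
                 sigma = as.numeric(vals[["sigma"]]),
                 x0_nonfocal = as.numeric(vals[["x0_nonfocal"]])),
            class = "epi_excitability")
}

#' Export a trajectory
#'
#' Delimited text (one row per sample: time, then each node's six
#' variables as `x1.k, y1.k, z.k, x2.k, y2.k, g.k`) or a compact binary
#' doubles container.  Either format gets a YAML metadata sidecar
#' (`<path>.meta.yml`) recording the parameters, x0 vector, sampling step
#' and layout.
#'
#' @param traj an `epi_trajectory`.
#' @param path output file.
#' @param format `"tsv"` or `"bin"` (raw little-endian doubles,
#'   row-major samples x (1 + 6 n) including the time column).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("tsv", "bin")) {
  stopifnot(inherits(traj, "epi_trajectory"))
  format <- match.arg(format)
  vars <- c("x1", "y1", "z", "x2", "y2", "g")
  mat <- cbind(traj$times,
               do.call(cbind, lapply(seq_len(traj$n), function(k)
                 sapply(vars, function(v) traj[[v]][, k]))))
  cols <- c("time", unlist(lapply(seq_len(traj$n), function(k)
    paste0(vars, ".", k))))
  if (format == "tsv") {
    colnames(mat) <- cols
    write.table(mat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(t(mat)), con, size = 8, endian = "little")
    close(con)
  }
  yaml::write_yaml(list(format = format, n_nodes = traj$n,
                        n_samples = length(traj$times), dt = traj$dt,
                        columns = cols, x0 = as.numeric(traj$x0),
                        params = unclass(traj$params)),
                   paste0(path, ".meta.yml"))
  invisible(path)
}
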