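#' Build the static wiring of the recurrent network
#'
#' Constructs the fixed connectivity blocks involving inhibitory neurons:
#' every neuron receives a fixed number of inhibitory contacts and every
#' inhibitory neuron a fixed number of excitatory contacts, with
#' presynaptic partners drawn uniformly with replacement (multapses are
#' counted as integer contact numbers) and self-connections excluded. The
#' excitatory-to-excitatory block starts empty; it exists only through the
#' structural-plasticity rule.
#'
#' Neurons are indexed globally: excitatory \code{1..n_e}, inhibitory
#' \code{n_e+1..n_e+n_i}.
#'
#' @param n_e,n_i numbers of excitatory and inhibitory neurons
#' @param params a [lif_params()] object
#' @param seed construction RNG seed
#' @param indegree optional list with elements \code{ei} (inhibitory
#'   contacts onto each excitatory neuron), \code{ie} (excitatory contacts
#'   onto each inhibitory neuron) and \code{ii}; defaults to the fractions
#'   \code{floor(0.1 * n_i)}, \code{floor(0.1 * n_e)}, \code{floor(0.1 *
#'   n_i)} of the respective source populations
#' @return an object of class \code{engram_conn} with components
#'   \code{static} and \code{ee} (integer triplet matrices with columns
#'   \code{pre}, \code{post}, \code{count}), \code{n_e}, \code{n_i}
#' @examples
#' conn <- build_static_network(100, 25, seed = 1)
#' head(conn$static)
#' @export
build_static_network <- function(n_e, n_i, params = lif_params(), seed = 1,
                                 indegree = NULL) {
  if (n_e <= 0 || n_i <= 0) stop("population sizes must be positive")
  if (is.null(indegree))
    indegree <- list(ei = floor(0.1 * n_i), ie = floor(0.1 * n_e),
                     ii = floor(0.1 * n_i))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  draw_block <- function(posts, sources, k, exclude_self = FALSE) {
    if (k <= 0) return(NULL)
    rows <- lapply(posts, function(p) {
      src <- if (exclude_self) setdiff(sources, p) else sources
      pre <- src[sample.int(length(src), k, replace = TRUE)]
      tab <- table(pre)
      cbind(pre = as.integer(names(tab)), post = rep.int(p, length(tab)),
            count = as.integer(tab))
    })
    do.call(rbind, rows)
  }
  e_idx <- seq_len(n_e)
  i_idx <- n_e + seq_len(n_i)
  static <- rbind(
    draw_block(e_idx, i_idx, indegree$ei),                 # I -> E
    draw_block(i_idx, e_idx, indegree$ie),                 # E -> I
    draw_block(i_idx, i_idx, indegree$ii, exclude_self = TRUE))  # I -> I
  if (is.null(static))
    static <- matrix(integer(), 0, 3,
                     dimnames = list(NULL, c("pre", "post", "count")))
  colnames(static) <- c("pre", "post", "count")
  structure(list(n_e = n_e, n_i = n_i, static = static,
                 ee = matrix(integer(), 0, 3,
                             dimnames = list(NULL,
                                             c("pre", "post", "count"))),
                 indegree = indegree, params = params),
            class = "engram_conn")
}

#' @export
print.engram_conn <- function(x, ...) {
  cat(sprintf("network connectivity: %d excitatory, %d inhibitory neurons\n",
              x$n_e, x$n_i))
  cat(sprintf("  static contacts: %d triplets; EE contacts: %d (%d triplets)\n",
              nrow(x$static), sum(x$ee[, 3]), nrow(x$ee)))
  invisible(x)
}

#' In- and out-degrees of the plastic excitatory block
#'
#' @param conn an \code{engram_conn} object
#' @return list with integer vectors \code{k_in} and \code{k_out} of EE
#'   contact counts per excitatory neuron
#' @export
ee_degrees <- function(conn) {
  k_in <- k_out <- integer(conn$n_e)
  if (nrow(conn$ee) > 0) {
    ki <- tapply(conn$ee[, 3], conn$ee[, 2], sum)
    ko <- tapply(conn$ee[, 3], conn$ee[, 1], sum)
    k_in[as.integer(names(ki))] <- as.integer(ki)
    k_out[as.integer(names(ko))] <- as.integer(ko)
  }
  list(k_in = k_in, k_out = k_out)
}

#' Static in-degree vectors of the network
#'
#' @param conn an \code{engram_conn} object
#' @return per-neuron in-degree of the static blocks (contacts)
#' @export
static_indegree <- function(conn) {
  n <- conn$n_e + conn$n_i
  k <- integer(n)
  ki <- tapply(conn$static[, 3], conn$static[, 2], sum)
  k[as.integer(names(ki))] <- as.integer(ki)
  k
}

#' Write and read spike records as two-column ASCII
#'
#' Spike files are plain text with two columns, \code{time_ms} and
#' \code{neuron}, time-sorted (the classic gdf layout plus a header line).
#'
#' @param spikes data frame with columns \code{time_ms}, \code{neuron}
#' @param path file path
#' @return \code{read_spikes} returns the spike data frame
#' @export
write_spikes <- function(spikes, path) {
  spikes <- spikes[order(spikes$time_ms), c("time_ms", "neuron")]
  write.table(spikes, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("numeric", "integer"))
}

#' Write and read connectivity snapshots as sparse triplet text
#'
#' @param conn an \code{engram_conn} object or a triplet matrix
#' @param path file path
#' @param block which block to write: \code{"ee"} or \code{"static"}
#' @return \code{read_connectivity} returns an integer triplet matrix
#' @export
write_connectivity <- function(conn, path, block = "ee") {
  m <- if (is.matrix(conn)) conn else conn[[block]]
  colnames(m) <- c("pre", "post", "count")
  write.table(m, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t",
                       colClasses = "integer"))
}

#' Dense contact-count matrix of the EE block (small networks)
#'
#' @param conn an \code{engram_conn} object
#' @return integer matrix \code{[post, pre]} of contact counts
#' @export
ee_matrix <- function(conn) {
  m <- matrix(0L, conn$n_e, conn$n_e)
  if (nrow(conn$ee) > 0)
    m[cbind(conn$ee[, 2], conn$ee[, 1])] <- conn$ee[, 3]
  m
}
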