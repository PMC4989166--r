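# Reading alignments and population metadata, recoding mutations, collapsing
# haplotypes and building mutational-step distance matrices.

#' Read an aligned multi-record FASTA
#'
#' Sequences are normalised to upper case and validated against the alphabet
#' \{A,C,G,T,N,-\}; unequal lengths are an error.
#'
#' @param path FASTA file of aligned sequences.
#' @param locusBounds optional list of \code{c(start, end)} 0-based half-open
#'   column ranges, one per concatenated spacer region; default is a single
#'   region spanning the alignment.
#' @return a \linkS4class{HapAlignment}
#' @export
readAlignment <- function(path, locusBounds = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("alignment file contains no records: ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("aligned sequences must all have the same length (found lengths ",
         paste(unique(w), collapse = ", "), ")")
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  HapAlignment(m, locusBounds)
}

#' Construct a HapAlignment from a character matrix
#'
#' @param seqs character matrix (samples x sites) with unique rownames.
#' @param locusBounds see \code{\link{readAlignment}}.
#' @export
HapAlignment <- function(seqs, locusBounds = NULL) {
  if (is.null(locusBounds)) locusBounds <- list(c(0L, ncol(seqs)))
  b <- do.call(rbind, lapply(locusBounds, function(x) as.integer(x[1:2])))
  colnames(b) <- c("start", "end")
  new("HapAlignment", seqs = seqs, locusBounds = b)
}

#' Read a population table
#'
#' Expects columns \code{population}, \code{latitude}, \code{longitude},
#' \code{sample_id}; each sample must belong to exactly one population and
#' coordinates must be valid WGS84 decimal degrees.
#'
#' @param path CSV file.
#' @return data.frame with one row per sample.
#' @export
readPopulationTable <- function(path) {
  if (!file.exists(path)) stop("population table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validatePopulationTable(tab)
}

#' @rdname readPopulationTable
#' @param tab a data.frame with the required columns.
#' @export
validatePopulationTable <- function(tab) {
  need <- c("population", "latitude", "longitude", "sample_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("population table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample_id in population table: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  if (any(abs(tab$latitude) > 90) || any(abs(tab$longitude) > 180))
    stop("coordinates out of range: |latitude| <= 90 and |longitude| <= 180 required")
  cc <- unique(tab[, c("population", "latitude", "longitude")])
  if (anyDuplicated(cc$population))
    stop("a population must have a single coordinate pair")
  tab
}

.revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN-", "TGCAN-", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Recode mutational events as single columns
#'
#' Produces the matrix of variable recoded columns on which haplotypes and
#' mutational-step distances are defined. Substitution sites are kept as-is;
#' each maximal gap run (distinct span) becomes one binary presence/absence
#' column; each user-declared inversion region becomes one binary orientation
#' column. Columns where any sample carries N, and substitution sites
#' overlapped by any gap run, are excluded so every event contributes exactly
#' one column and recoded vectors are fully determined.
#'
#' @param a a \linkS4class{HapAlignment}.
#' @param inversions optional list of \code{c(start, end)} 0-based half-open
#'   column ranges declared as inversions; ranges must not overlap.
#' @return a \linkS4class{MutationMatrix}
#' @export
recodeMutations <- function(a, inversions = NULL) {
  stopifnot(is(a, "HapAlignment"))
  m <- a@seqs
  L <- ncol(m)
  nS <- nrow(m)
  consumed <- rep(FALSE, L)      # sites represented by an event column
  excluded <- colSums(m == "N") > 0L

  cols <- list(); meta <- list()

  ## inversions: one binary orientation column per declared range
  if (!is.null(inversions) && length(inversions)) {
    iv <- do.call(rbind, lapply(inversions, function(x) as.integer(x[1:2])))
    if (any(iv[, 1L] < 0L) || any(iv[, 2L] > L) || any(iv[, 2L] <= iv[, 1L]))
      stop("inversion ranges must be non-empty and lie within [0, L)")
    o <- order(iv[, 1L]); iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop("overlapping inversion ranges")
    for (r in seq_len(nrow(iv))) {
      idx <- (iv[r, 1L] + 1L):iv[r, 2L]
      if (any(excluded[idx])) next
      sub <- apply(m[, idx, drop = FALSE], 1L, paste, collapse = "")
      ref <- sub[[1L]]
      rc <- .revcomp(ref)
      refv <- strsplit(ref, "")[[1L]]; rcv <- strsplit(rc, "")[[1L]]
      state <- vapply(sub, function(s) {
        sv <- strsplit(s, "")[[1L]]
        if (sum(sv != rcv) < sum(sv != refv)) "V" else "R"
      }, character(1L))
      consumed[idx] <- TRUE
      if (length(unique(state)) > 1L) {
        cols[[length(cols) + 1L]] <- unname(state)
        meta[[length(meta) + 1L]] <- data.frame(
          type = "inversion", start = iv[r, 1L] + 1L, end = iv[r, 2L])
      }
    }
  }

  ## indels: one presence/absence column per distinct maximal gap span
  gapRuns <- lapply(seq_len(nS), function(i) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cbind(starts, ends)[r$values, , drop = FALSE]
  })
  spans <- unique(do.call(rbind, gapRuns))
  if (!is.null(spans) && nrow(spans)) {
    spans <- spans[order(spans[, 1L], spans[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(spans))) {
      idx <- spans[r, 1L]:spans[r, 2L]
      if (any(consumed[idx]) || any(excluded[idx])) next
      has <- vapply(gapRuns, function(g)
        any(g[, 1L] == spans[r, 1L] & g[, 2L] == spans[r, 2L]), logical(1L))
      state <- ifelse(has, "P", "A")
      if (length(unique(state)) > 1L) {
        cols[[length(cols) + 1L]] <- state
        meta[[length(meta) + 1L]] <- data.frame(
          type = "indel", start = spans[r, 1L], end = spans[r, 2L])
      }
    }
    for (r in seq_len(nrow(spans))) consumed[spans[r, 1L]:spans[r, 2L]] <- TRUE
  }

  ## substitutions at the remaining sites
  for (s in which(!consumed & !excluded)) {
    col <- m[, s]
    if (length(unique(col)) > 1L) {
      cols[[length(cols) + 1L]] <- col
      meta[[length(meta) + 1L]] <- data.frame(
        type = "substitution", start = s, end = s)
    }
  }

  if (length(cols)) {
    metaDf <- do.call(rbind, meta)
    o <- order(metaDf$start, metaDf$end)
    states <- do.call(cbind, cols)[, o, drop = FALSE]
    metaDf <- metaDf[o, , drop = FALSE]
    rownames(metaDf) <- NULL
  } else {
    states <- matrix(character(0), nrow = nS, ncol = 0L)
    metaDf <- data.frame(type = character(0), start = integer(0),
                         end = integer(0))
  }
  rownames(states) <- rownames(m)
  new("MutationMatrix", states = states, meta = metaDf,
      alignmentLength = L)
}

#' Collapse samples into distinct haplotypes
#'
#' Haplotypes are numbered in order of first appearance in the sample order
#' and labelled \code{<prefix><rank>} (mirroring CH1..., MH1..., SH1...).
#'
#' @param m a \linkS4class{MutationMatrix}.
#' @param pops optional population table (see
#'   \code{\link{readPopulationTable}}); when supplied, the per-population
#'   haplotype count table is populated, otherwise all samples are pooled.
#' @param labelPrefix haplotype label prefix.
#' @return a \linkS4class{HaplotypeSet}
#' @export
collapseHaplotypes <- function(m, pops = NULL, labelPrefix = "H") {
  stopifnot(is(m, "MutationMatrix"))
  if (nrow(m@states) < 1L) stop("at least one sample required")
  key <- apply(m@states, 1L, paste, collapse = "\r")
  uk <- unique(key)
  labels <- paste0(labelPrefix, seq_along(uk))
  hap <- labels[match(key, uk)]
  names(hap) <- rownames(m@states)
  vectors <- m@states[match(uk, key), , drop = FALSE]
  rownames(vectors) <- labels

  if (is.null(pops)) {
    popOf <- setNames(rep("all", length(hap)), names(hap))
  } else {
    miss <- setdiff(names(hap), pops$sample_id)
    if (length(miss)) stop("samples missing from population table: ",
                           paste(miss, collapse = ", "))
    popOf <- setNames(pops$population[match(names(hap), pops$sample_id)],
                      names(hap))
  }
  counts <- table(factor(popOf, levels = unique(popOf)),
                  factor(hap, levels = labels))
  popCounts <- matrix(as.integer(counts), nrow = nrow(counts),
                      dimnames = dimnames(counts))

  new("HaplotypeSet", labels = labels, vectors = vectors, membership = hap,
      popCounts = popCounts, meta = m@meta,
      alignmentLength = m@alignmentLength,
      monomorphic = length(uk) == 1L)
}

#' Pairwise mutational-step distances between haplotypes
#'
#' Each recoded column (substitution site, indel event, inversion event)
#' contributes one step.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param includeIndels drop indel/inversion columns when FALSE.
#' @return symmetric integer matrix with haplotype labels as dimnames.
#' @export
pairwiseDifferences <- function(h, includeIndels = TRUE) {
  stopifnot(is(h, "HaplotypeSet"))
  v <- h@vectors
  if (!includeIndels) v <- v[, h@meta$type == "substitution", drop = FALSE]
  if (nrow(v) < 2L)
    warning("single haplotype: degenerate 1x1 distance matrix")
  .hammingMatrix(v)
}

#' Write a HaplotypeSet to CSV files
#'
#' Emits a membership table (sample, population, haplotype) and a
#' per-population haplotype count table.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param membershipFile,countsFile output CSV paths.
#' @export
writeHaplotypeSet <- function(h, membershipFile, countsFile) {
  mem <- data.frame(sample_id = names(h@membership),
                    haplotype = unname(h@membership))
  write.csv(mem, membershipFile, row.names = FALSE)
  cnt <- data.frame(population = rownames(h@popCounts), h@popCounts,
                    check.names = FALSE)
  write.csv(cnt, countsFile, row.names = FALSE)
  invisible(NULL)
}

#' Write a distance matrix as square CSV with haplotype-id header
#' @param d distance matrix from \code{\link{pairwiseDifferences}}.
#' @param file output CSV path.
#' @export
writeDistanceMatrix <- function(d, file) {
  write.csv(data.frame(haplotype = rownames(d), d, check.names = FALSE),
            file, row.names = FALSE)
  invisible(NULL)
}
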