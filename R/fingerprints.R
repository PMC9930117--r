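#' 2D molecular fingerprints
#'
#' Four fingerprint schemes drive the similarity screen:
#'
#' * **MACCS** structural keys: a fixed 166-position key vector; position k
#'   is set when the k-th public MACCS SMARTS pattern matches.
#' * **radial**: circular atom environments grown over a configurable number
#'   of iterations (default 2) around every heavy atom, atoms typed by the
#'   daylight scheme (atomic number, valence, formal charge, H connections,
#'   heavy connections), each environment canonicalised and hashed.
#' * **dendritic**: all linear paths and single-branch tree fragments with
#'   up to five bonds, same typing, canonicalised and hashed.
#' * **MOLPRINT2D**: one environment per heavy atom listing the SYBYL-typed
#'   neighbours within two bonds.
#'
#' The hashed (sparse) schemes store only the "on" bits of a \eqn{2^{32}}
#' bit space; the hash is the pinned FNV-1a function ([fnv1a32()]), so bit
#' sets are reproducible and invariant under atom renumbering.  Collisions
#' are accepted, as usual for bit-scaled hashed fingerprints.
#'
#' @name vsfuse-fingerprints
NULL

FP_KINDS <- c("maccs", "radial", "dendritic", "molprint2d")

# --- graph helpers -------------------------------------------------------

graph_components <- function(graph) {
  n <- nrow(graph$atoms)
  if (n == 0) return(integer(0))
  comp <- integer(n)
  nbr <- vector("list", n)
  for (e in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[e]; j <- graph$bonds$j[e]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[u] > 0) next
      comp[u] <- cur
      stack <- c(stack, nbr[[u]])
    }
  }
  comp
}

# Number of aromatic rings = cycle rank of the aromatic-bond subgraph,
# summed over its connected components (equals the SSSR count).
n_aromatic_rings <- function(graph) {
  ar <- graph$bonds[graph$bonds$token == ":", , drop = FALSE]
  if (nrow(ar) == 0) return(0L)
  verts <- sort(unique(c(ar$i, ar$j)))
  sub <- list(atoms = graph$atoms[verts, , drop = FALSE],
              bonds = tibble(i = match(ar$i, verts), j = match(ar$j, verts),
                             token = ar$token))
  comp <- graph_components(sub)
  n_comp <- length(unique(comp))
  as.integer(nrow(ar) - length(verts) + n_comp)
}

# Aromatic rings as atom-index sets: smallest cycle through each aromatic
# bond (breadth-first shortest path between the endpoints avoiding the bond
# itself), de-duplicated.  Adequate for ordinary fused ring systems.
aromatic_rings <- function(graph) {
  ar <- graph$bonds[graph$bonds$token == ":", , drop = FALSE]
  if (nrow(ar) == 0) return(list())
  n <- nrow(graph$atoms)
  nbr <- vector("list", n)
  for (e in seq_len(nrow(ar))) {
    nbr[[ar$i[e]]] <- c(nbr[[ar$i[e]]], ar$j[e])
    nbr[[ar$j[e]]] <- c(nbr[[ar$j[e]]], ar$i[e])
  }
  rings <- list()
  for (e in seq_len(nrow(ar))) {
    a <- ar$i[e]; b <- ar$j[e]
    # BFS from a to b not using edge (a,b)
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[a] <- 0L
    q <- a
    while (length(q) && is.na(dist[b])) {
      u <- q[1]; q <- q[-1]
      for (v in nbr[[u]]) {
        if (u == a && v == b) next
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L; prev[v] <- u; q <- c(q, v)
        }
      }
    }
    if (is.na(dist[b])) next
    path <- b
    while (path[1] != a) path <- c(prev[path[1]], path)
    rings[[length(rings) + 1]] <- sort(path)
  }
  unique(rings)
}

# --- fingerprint builders ------------------------------------------------

#' Radial (circular) fingerprint of one molecular graph
#'
#' @param graph molecular graph (element of the `graph` column).
#' @param iterations number of radial growth iterations (default 2).
#' @return sorted numeric vector of on-bits in `[0, 2^32)`, with attribute
#'   `kind = "radial"`.
#' @export
fp_radial <- function(graph, iterations = 2) {
  bits <- cpp_radial_bits(graph$atoms$daylight,
                          graph$bonds$i, graph$bonds$j, graph$bonds$token,
                          as.integer(iterations))
  structure(bits, kind = "radial")
}

#' Dendritic fingerprint of one molecular graph
#'
#' @param graph molecular graph.
#' @param max_bonds fragment size cap in bonds (default 5).
#' @return sorted numeric on-bit vector, attribute `kind = "dendritic"`.
#' @export
fp_dendritic <- function(graph, max_bonds = 5) {
  bits <- cpp_dendritic_bits(graph$atoms$daylight,
                             graph$bonds$i, graph$bonds$j, graph$bonds$token,
                             as.integer(max_bonds))
  structure(bits, kind = "dendritic")
}

#' MOLPRINT2D fingerprint of one molecular graph
#'
#' @param graph molecular graph.
#' @return sorted numeric on-bit vector, attribute `kind = "molprint2d"`.
#' @export
fp_molprint2d <- function(graph) {
  bits <- cpp_molprint_bits(graph$atoms$sybyl,
                            graph$bonds$i, graph$bonds$j, graph$bonds$token)
  structure(bits, kind = "molprint2d")
}

#' MACCS structural keys for a molecule library
#'
#' Evaluates the public 166-key set over a whole molecule tibble (the SMARTS
#' engine is batched over the library, so this is the efficient entry
#' point).  Keys are returned as sorted vectors of set key numbers; a key is
#' set when its pattern has strictly more unique matches than its count
#' threshold.  Key 1 (isotope) is never set; key 125 (>1 aromatic ring) and
#' key 166 (>1 fragment) are computed from the molecular graph.
#'
#' @param mols molecule tibble.
#' @return named list (by compound id) of sorted integer key vectors, each
#'   with attribute `kind = "maccs"`.
#' @export
fp_maccs <- function(mols) {
  stopifnot(nrow(mols) > 0)
  tab <- maccs_key_table()
  refs <- obmols_from_smiles(mols$smiles, mols$id)
  res <- matrix(FALSE, nrow(mols), 166)
  for (r in seq_len(nrow(tab))) {
    if (tab$smarts[r] == "?") next
    counts <- suppressWarnings(
      ChemmineOB::smartsSearch_OB(refs, tab$smarts[r]))
    res[, tab$key[r]] <- counts > tab$threshold[r]
  }
  for (k in seq_len(nrow(mols))) {
    g <- mols$graph[[k]]
    res[k, 125] <- n_aromatic_rings(g) > 1
    res[k, 166] <- length(unique(graph_components(g))) > 1
  }
  out <- lapply(seq_len(nrow(mols)), function(k)
    structure(as.numeric(which(res[k, ])), kind = "maccs"))
  names(out) <- mols$id
  out
}

#' Compute a fingerprint table for a molecule library
#'
#' @param mols molecule tibble.
#' @param kinds subset of `c("maccs", "radial", "dendritic", "molprint2d")`.
#' @param radial_iterations,dendritic_max_bonds scheme parameters.
#' @return tibble with columns `id`, `kind`, `bits` (list of sorted on-bit
#'   vectors; MACCS keys are positions 1..166).
#' @examples
#' mols <- parse_molecules(c("CCO", "CCN"), c("a", "b"))
#' fingerprint_table(mols, kinds = "radial")
#' @export
fingerprint_table <- function(mols, kinds = FP_KINDS,
                              radial_iterations = 2,
                              dendritic_max_bonds = 5) {
  kinds <- match.arg(kinds, FP_KINDS, several.ok = TRUE)
  stopifnot(nrow(mols) > 0)
  parts <- list()
  if ("maccs" %in% kinds) {
    parts$maccs <- tibble(id = mols$id, kind = "maccs",
                          bits = unname(fp_maccs(mols)))
  }
  if ("radial" %in% kinds) {
    parts$radial <- tibble(id = mols$id, kind = "radial",
                           bits = map(mols$graph, fp_radial,
                                      iterations = radial_iterations))
  }
  if ("dendritic" %in% kinds) {
    parts$dendritic <- tibble(id = mols$id, kind = "dendritic",
                              bits = map(mols$graph, fp_dendritic,
                                         max_bonds = dendritic_max_bonds))
  }
  if ("molprint2d" %in% kinds) {
    parts$molprint2d <- tibble(id = mols$id, kind = "molprint2d",
                               bits = map(mols$graph, fp_molprint2d))
  }
  bind_rows(parts)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over on-bit sets.  Two empty fingerprints
#' have similarity 0 by convention (documented, since the empty molecule
#' carries no evidence of similarity).  Comparing fingerprints of different
#' kinds is an error.
#'
#' @param a,b fingerprints (sorted on-bit vectors with a `kind` attribute).
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(structure(c(1, 2, 3), kind = "radial"),
#'          structure(c(2, 3, 9), kind = "radial"))
#' @export
tanimoto <- function(a, b) {
  ka <- attr(a, "kind"); kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb))
    abort(paste0("fingerprint kind mismatch: ", ka, " vs ", kb))
  cpp_tanimoto_matrix(list(as.numeric(a)), list(as.numeric(b)))[1, 1]
}

#' Tanimoto similarity matrix between two fingerprint lists
#'
#' @param fps_a,fps_b lists of sorted on-bit vectors (same kind).
#' @return `length(fps_a)` x `length(fps_b)` similarity matrix.
#' @export
tanimoto_matrix <- function(fps_a, fps_b) {
  m <- cpp_tanimoto_matrix(lapply(fps_a, as.numeric),
                           lapply(fps_b, as.numeric))
  rownames(m) <- names(fps_a)
  colnames(m) <- names(fps_b)
  m
}

#' Serialise fingerprints to a plain-text file
#'
#' One line per compound: `id<TAB>kind<TAB>comma-separated sorted on-bits`.
#' MACCS fingerprints are additionally representable as a 166-character 0/1
#' string via [maccs_string()].
#'
#' @param fps fingerprint table from [fingerprint_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  lines <- sprintf("%s\t%s\t%s", fps$id, fps$kind,
                   vapply(fps$bits, function(b)
                     paste(format(as.numeric(b), scientific = FALSE,
                                  trim = TRUE), collapse = ","),
                     character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    id = vapply(parts, `[[`, character(1), 1),
    kind = vapply(parts, `[[`, character(1), 2),
    bits = lapply(parts, function(p) {
      b <- if (length(p) < 3 || !nzchar(p[3])) numeric(0)
           else as.numeric(strsplit(p[3], ",", fixed = TRUE)[[1]])
      structure(b, kind = p[2])
    })
  )
}

#' MACCS fingerprint as a 166-character 0/1 string
#'
#' @param keys a MACCS fingerprint (vector of set key numbers).
#' @return character scalar of length 166.
#' @export
maccs_string <- function(keys) {
  v <- rep("0", 166)
  v[as.integer(keys)] <- "1"
  paste(v, collapse = "")
}
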