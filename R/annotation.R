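# monoisotopic atomic masses (Da) and the electron mass, used both by the
# formula parser and by the build-time validation of the adduct shifts
ATOMIC_MASS <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
                 P = 30.97376200, S = 31.97207117, Cl = 34.96885268,
                 Na = 22.98976928, K = 38.96370649, electron = 0.00054858)

# hard-coded negative-mode adduct mass shifts (Da added to the neutral
# monoisotopic mass, singly charged); validated against ATOMIC_MASS on access
ADDUCT_SHIFTS <- c(
  "M-H"     = -1.00727645,
  "M-H2O-H" = -19.01784113,
  "M+Na-2H" = 20.97466780,
  "M+K-2H"  = 36.94860501,
  "M+Cl"    = 34.96940126)

# recompute each shift from atomic masses (an [M+X]- ion carries one extra
# electron relative to its neutral atom composition)
computed_adduct_shifts <- function() {
  m <- ATOMIC_MASS
  c("M-H"     = -(m[["H"]] - m[["electron"]]),
    "M-H2O-H" = -(2 * m[["H"]] + m[["O"]]) - (m[["H"]] - m[["electron"]]),
    "M+Na-2H" = m[["Na"]] - 2 * m[["H"]] + m[["electron"]],
    "M+K-2H"  = m[["K"]] - 2 * m[["H"]] + m[["electron"]],
    "M+Cl"    = m[["Cl"]] + m[["electron"]])
}

#' Negative-mode adduct rules
#'
#' The five singly charged negative adducts used for metabolite annotation:
#' \[M-H\]-, \[M-H2O-H\]-, \[M+Na-2H\]-, \[M+K-2H\]- and \[M+Cl\]-. The
#' hard-coded shifts are re-derived from monoisotopic atomic masses (including
#' the electron) on every access and must agree to 1e-6 Da.
#'
#' @return data.frame `name`, `mass_shift` (Da), `charge` (-1).
#' @export
adduct_rules <- function() {
  chk <- computed_adduct_shifts()
  stopifnot(all(abs(chk[names(ADDUCT_SHIFTS)] - ADDUCT_SHIFTS) < 1e-6))
  data.frame(name = names(ADDUCT_SHIFTS), mass_shift = unname(ADDUCT_SHIFTS),
             charge = -1L, stringsAsFactors = FALSE)
}

#' Observed m/z of a neutral metabolite under an adduct rule
#'
#' @param neutral_mass monoisotopic neutral mass in Da (> 0).
#' @param rule adduct name, one of `adduct_rules()$name`.
#' @return m/z of the singly charged negative ion.
#' @export
adduct_mz <- function(neutral_mass, rule) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0", call. = FALSE)
  if (!rule %in% names(ADDUCT_SHIFTS))
    stop(sprintf("unknown adduct rule '%s'", rule), call. = FALSE)
  adduct_rules() # triggers the shift validation
  neutral_mass + ADDUCT_SHIFTS[[rule]]
}

#' Monoisotopic mass from a molecular formula
#'
#' Supports element symbols C, H, N, O, P, S, Cl, Na, K with optional counts
#' (e.g. `"C6H12O6"`).
#'
#' @param formula character formula.
#' @return monoisotopic mass in Da.
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1L]]
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1L]]
    if (!length(toks) || paste(toks, collapse = "") != f)
      stop(sprintf("cannot parse formula '%s'", f), call. = FALSE)
    total <- 0
    for (tk in toks) {
      el <- gsub("[0-9]", "", tk)
      ct <- gsub("[^0-9]", "", tk)
      n <- if (ct == "") 1L else as.integer(ct)
      if (!el %in% names(ATOMIC_MASS) || el == "electron")
        stop(sprintf("unsupported element '%s' in '%s'", el, f), call. = FALSE)
      total <- total + ATOMIC_MASS[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a metabolite monoisotopic-mass table
#'
#' @param path TSV with columns `id`, `monoisotopic_mass` and optionally
#'   `formula`, `name`.
#' @return data.frame.
#' @export
read_mass_table <- function(path) {
  df <- read_tsv(path)
  if (!all(c("id", "monoisotopic_mass") %in% names(df)))
    stop("mass table needs columns id and monoisotopic_mass", call. = FALSE)
  df$monoisotopic_mass <- as.numeric(df$monoisotopic_mass)
  if (anyNA(df$monoisotopic_mass) || any(df$monoisotopic_mass <= 0))
    stop("malformed mass table: non-positive or missing masses", call. = FALSE)
  df
}

#' Annotate observed peaks with candidate metabolites
#'
#' Reports every (peak, metabolite, adduct) triple whose theoretical adduct
#' m/z lies within `tol_ppm` of the observed peak; multiple hits per peak are
#' allowed and ranked by absolute ppm error.
#'
#' @param peaks a `peak_list` or numeric m/z vector.
#' @param mass_table data.frame from [read_mass_table()] (columns `id`,
#'   `monoisotopic_mass`).
#' @param tol_ppm tolerance in ppm (> 0; default 4, appropriate for FT-ICR
#'   mass accuracy).
#' @return data.frame `observed_mz`, `metabolite_id`, `neutral_mass`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, sorted by peak then |ppm|.
#' @export
annotate_peaks <- function(peaks, mass_table, tol_ppm = 4) {
  mz <- if (is.numeric(peaks)) peaks else peaks$mz
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  rules <- adduct_rules()
  empty <- data.frame(observed_mz = numeric(0), metabolite_id = character(0),
                      neutral_mass = numeric(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0))
  if (!nrow(mass_table) || !length(mz)) return(empty)
  theo <- expand.grid(met = seq_len(nrow(mass_table)),
                      rule = seq_len(nrow(rules)))
  theo$mz <- mass_table$monoisotopic_mass[theo$met] + rules$mass_shift[theo$rule]
  hits <- lapply(mz, function(obs) {
    ppm <- (obs - theo$mz) / theo$mz * 1e6
    sel <- which(abs(ppm) <= tol_ppm)
    if (!length(sel)) return(NULL)
    sel <- sel[order(abs(ppm[sel]))]
    data.frame(observed_mz = obs,
               metabolite_id = as.character(mass_table$id[theo$met[sel]]),
               neutral_mass = mass_table$monoisotopic_mass[theo$met[sel]],
               adduct = rules$name[theo$rule[sel]],
               theoretical_mz = theo$mz[sel],
               ppm_error = ppm[sel], stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

#' Read pathway membership sets in GMT format
#'
#' @param path GMT file: one pathway per line, tab-separated
#'   `id<TAB>description<TAB>member...`.
#' @return named list of member character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT: every line needs id, description, members",
                     call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Pathway over-representation by the hypergeometric test
#'
#' One-sided hypergeometric p per pathway (pathways intersected with the
#' universe first), Benjamini-Hochberg q across pathways; significant iff
#' q < 0.05.
#'
#' @param query character vector of metabolite ids (subset of `universe`).
#' @param universe character vector of all annotated metabolite ids.
#' @param pathways named list of member vectors ([read_gmt()]).
#' @return data.frame of class `enrichment_result`: `pathway`, `overlap`,
#'   `pathway_size`, `query_size`, `universe_size`, `p`, `q`, `significant`.
#' @export
enrich_pathways <- function(query, universe, pathways) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop("query must be a subset of the universe", call. = FALSE)
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], universe)
    ov <- length(intersect(query, members))
    p <- phyper(ov - 1, length(members), N - length(members), nq,
                lower.tail = FALSE)
    data.frame(pathway = pw, overlap = ov, pathway_size = length(members),
               query_size = nq, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < 0.05
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Spearman correlation network of metabolite channels
#'
#' Spearman rho for every channel pair across the pixels of one
#' subpopulation; pair p-values (asymptotic t approximation) are
#' Benjamini-Hochberg adjusted over all pairs and edges are kept where the
#' adjusted p < `alpha`. Edges carry a sign (positive/negative) and weight
#' |rho|. Constant channels are excluded with a message.
#'
#' @param intensities pixels x channels matrix restricted to one
#'   subpopulation's pixels (>= 10 pixels).
#' @param channel_ids identifiers for the columns (default column index).
#' @param direction optional named direction attribute per channel (node
#'   metadata, e.g. from [differential_metabolites()]).
#' @param alpha adjusted-p cutoff for edges (default 0.05).
#' @return object of class `metabolite_network`: `nodes` (data.frame `id`,
#'   `direction`), `edges` (data.frame `from`, `to`, `rho`, `p_adj`, `sign`,
#'   `weight`), `n_pixels`.
#' @export
correlation_network <- function(intensities, channel_ids = NULL,
                                direction = NULL, alpha = 0.05) {
  x <- as.matrix(intensities)
  if (nrow(x) < 10L) stop("need >= 10 pixels", call. = FALSE)
  ids <- as.character(channel_ids %||% seq_len(ncol(x)))
  keep <- apply(x, 2L, function(col) length(unique(col)) > 1L)
  if (!all(keep)) {
    message(sprintf("excluding %d constant channel(s) from the network",
                    sum(!keep)))
    x <- x[, keep, drop = FALSE]
    ids <- ids[keep]
  }
  if (ncol(x) < 2L) stop("need >= 2 non-constant channels", call. = FALSE)
  n <- nrow(x)
  rho <- cor(x, method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  tstat <- r * sqrt((n - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p_adj <- bh_adjust(p)
  sel <- which(p_adj < alpha)
  edges <- data.frame(from = ids[ut[sel, 1L]], to = ids[ut[sel, 2L]],
                      rho = r[sel], p_adj = p_adj[sel],
                      sign = ifelse(r[sel] >= 0, "positive", "negative"),
                      weight = abs(r[sel]), stringsAsFactors = FALSE)
  dirv <- rep("ns", length(ids))
  if (!is.null(direction)) {
    hit <- match(ids, names(direction))
    dirv[!is.na(hit)] <- direction[hit[!is.na(hit)]]
  }
  structure(list(nodes = data.frame(id = ids, direction = dirv,
                                    stringsAsFactors = FALSE),
                 edges = edges, n_pixels = n),
            class = "metabolite_network")
}

#' @export
print.metabolite_network <- function(x, ...) {
  cat(sprintf("<metabolite_network> %d nodes, %d edges (%d positive / %d negative), %d pixels\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative"), x$n_pixels))
  invisible(x)
}

#' Export a metabolite network
#'
#' Writes the edge list as TSV and, optionally, GraphML via igraph.
#'
#' @param network a `metabolite_network`.
#' @param edge_path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(network, edge_path, graphml_path = NULL) {
  stopifnot(inherits(network, "metabolite_network"))
  write_tsv(network$edges, edge_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
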