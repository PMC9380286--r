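#' Configuration for a synthetic input bundle
#'
#' Defaults emulate the scale and shape of a yeast-sized benchmark at desk
#' scale: a heavy-tailed (preferential-attachment) interaction network,
#' time-course expression with module-level co-expression, a small
#' tree-shaped ontology with deep module-specific terms, and orthology
#' counts drawn from well-separated distributions for essential versus
#' background proteins.
#'
#' @param n_nodes Number of proteins (default 500).
#' @param pa_m Edges attached per node in the preferential-attachment model
#'   (default 4, average degree about 8 — comparable to curated yeast PINs).
#' @param n_essential Number of planted essential proteins (default 50).
#' @param m_samples Expression sampling points (default 36, the length of a
#'   typical yeast metabolic-cycle time course).
#' @param rho Within-module pairwise expression correlation target in
#'   `[0, 1]` (default 0.8).
#' @param dag_depth,dag_branching Depth and branching factor of the
#'   synthetic ontology tree (defaults 4 and 3: 81 leaves, enough to give
#'   each essential module its own deep term).
#' @param n_species Total reference species `N` for orthology (default 100).
#' @param p_ortho_essential,p_ortho_background Per-species ortholog
#'   probabilities for essential (0.75) and background (0.15) proteins;
#'   binomial counts from these are separated by far more than 3 standard
#'   deviations at `N = 100`.
#' @param graph_model `"pa"` (preferential attachment, default) or
#'   `"gnm"` (Erdos-Renyi with the same expected edge count, for null
#'   tests).
#' @param seed RNG seed; the same seed yields a byte-identical bundle.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nodes = 500L, pa_m = 4L, n_essential = 50L,
                             m_samples = 36L, rho = 0.8,
                             dag_depth = 4L, dag_branching = 3L,
                             n_species = 100L,
                             p_ortho_essential = 0.75,
                             p_ortho_background = 0.15,
                             graph_model = c("pa", "gnm"),
                             seed = 1L) {
  graph_model <- match.arg(graph_model)
  cfg <- list(n_nodes = as.integer(n_nodes), pa_m = as.integer(pa_m),
              n_essential = as.integer(n_essential),
              m_samples = as.integer(m_samples), rho = rho,
              dag_depth = as.integer(dag_depth),
              dag_branching = as.integer(dag_branching),
              n_species = as.integer(n_species),
              p_ortho_essential = p_ortho_essential,
              p_ortho_background = p_ortho_background,
              graph_model = graph_model, seed = as.integer(seed))
  stopifnot(cfg$n_nodes > 2, cfg$pa_m >= 1, cfg$m_samples >= 2,
            cfg$n_essential >= 1, cfg$n_essential < cfg$n_nodes,
            cfg$rho >= 0, cfg$rho <= 1,
            cfg$dag_depth >= 1, cfg$dag_branching >= 1,
            cfg$n_species >= 1,
            cfg$p_ortho_essential >= 0, cfg$p_ortho_essential <= 1,
            cfg$p_ortho_background >= 0, cfg$p_ortho_background <= 1)
  if (cfg$pa_m > cfg$n_nodes - 1) {
    stop("pa_m edges per node exceed the simple-graph maximum")
  }
  if (cfg$dag_branching^cfg$dag_depth < cfg$n_essential) {
    stop("ontology tree has fewer leaves (", cfg$dag_branching^cfg$dag_depth,
         ") than essential modules (", cfg$n_essential, ")")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic bundle in memory
#'
#' Same planted structure as [generate_bundle()] but returned as R objects
#' without touching disk: `edges`, `expression`, `dag`, `annotations`,
#' `orthology`, the planted `essential` identifiers and the per-node
#' `module` assignment. The caller's RNG state is restored on exit.
#'
#' @param config A [synthetic_config].
#' @return A named list (see above).
#' @export
generate_bundle_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  n <- config$n_nodes
  ids <- sprintf("P%04d", seq_len(n))

  ## interaction network: heavy-tailed degrees, or an ER null
  g <- if (config$graph_model == "pa") {
    igraph::sample_pa(n, power = 1, m = config$pa_m, directed = FALSE)
  } else {
    igraph::sample_gnm(n, min(config$pa_m * n, n * (n - 1) / 2))
  }
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(u = ids[el[, 1]], v = ids[el[, 2]],
                      stringsAsFactors = FALSE)

  ## planted essentials: sampled with probability proportional to degree, so
  ## their mean degree is elevated but the set is not simply the top-degree
  ## list (degree centrality alone must not recover them perfectly)
  deg <- igraph::degree(g)
  essential_idx <- sort(sample.int(n, config$n_essential, prob = deg + 1e-9))
  essential <- ids[essential_idx]

  ## modules: each essential anchors a module consisting of itself and its
  ## non-essential neighbors; a background node adjacent to several
  ## essentials joins the first one (by index)
  module <- integer(n)                      # 0 = background, else module id
  module[essential_idx] <- seq_along(essential_idx)
  nbrs <- igraph::adjacent_vertices(g, essential_idx)
  for (mi in seq_along(essential_idx)) {
    for (v in as.integer(nbrs[[mi]])) {
      if (module[[v]] == 0L) module[[v]] <- mi
    }
  }

  ## expression: shared latent factor per module + independent noise;
  ## factor loading sqrt(rho) gives within-module pairwise correlation ~ rho
  m <- config$m_samples
  factors <- matrix(stats::rnorm(config$n_essential * m),
                    nrow = config$n_essential)
  expr <- matrix(0, nrow = n, ncol = m, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    noise <- stats::rnorm(m)
    expr[i, ] <- if (module[[i]] > 0) {
      sqrt(config$rho) * factors[module[[i]], ] +
        sqrt(1 - config$rho) * noise
    } else {
      noise
    }
  }

  ## ontology: rooted tree, is_a edges except every fifth edge part_of;
  ## each module gets its own deepest leaf, background nodes shallow terms
  dag_info <- synthetic_dag(config$dag_depth, config$dag_branching)
  leaf_terms <- dag_info$leaves[seq_len(config$n_essential)]
  shallow_terms <- dag_info$depth1
  ann_prot <- character(0); ann_term <- character(0)
  for (i in seq_len(n)) {
    terms_i <- if (module[[i]] > 0) {
      lf <- leaf_terms[[module[[i]]]]
      c(lf, dag_info$dag$parents[[lf]][1])
    } else {
      shallow_terms[[sample.int(length(shallow_terms), 1)]]
    }
    ann_prot <- c(ann_prot, rep(ids[[i]], length(terms_i)))
    ann_term <- c(ann_term, terms_i)
  }
  annotations <- annotation_list(ann_prot, ann_term)

  ## orthology: binomial counts, essential vs background means separated by
  ## (p_e - p_b) * N >> 3 pooled standard deviations at the defaults
  n_u <- integer(n)
  is_ess <- seq_len(n) %in% essential_idx
  n_u[is_ess] <- stats::rbinom(sum(is_ess), config$n_species,
                               config$p_ortho_essential)
  n_u[!is_ess] <- stats::rbinom(sum(!is_ess), config$n_species,
                                config$p_ortho_background)
  orth <- orthology(stats::setNames(n_u, ids), config$n_species)

  list(config = config, ids = ids, edges = edges, expression = expr,
       dag = dag_info$dag, annotations = annotations, orthology = orth,
       essential = essential, module = module)
}

# full dag_branching-ary tree of the given depth; term ids GO:1000000 + i
synthetic_dag <- function(depth, branching) {
  terms <- "GO:1000000"
  parents <- list("GO:1000000" = character(0))
  types <- list("GO:1000000" = character(0))
  levels <- list("GO:1000000")
  counter <- 0L
  edge_i <- 0L
  for (d in seq_len(depth)) {
    lvl <- character(0)
    for (par in levels[[d]]) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        tm <- sprintf("GO:%07d", 1000000L + counter)
        edge_i <- edge_i + 1L
        terms <- c(terms, tm)
        parents[[tm]] <- par
        types[[tm]] <- if (edge_i %% 5L == 0L) "part_of" else "is_a"
        lvl <- c(lvl, tm)
      }
    }
    levels[[d + 1L]] <- lvl
  }
  list(dag = go_dag(terms, parents, types),
       leaves = levels[[depth + 1L]], depth1 = levels[[2L]])
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes the five input files consumed by the pipeline, plus a JSON
#' manifest recording the configuration:
#' `ppi.tsv` (edge list), `expression.tsv`, `go.obo`, `annotations.gaf`,
#' `orthology.tsv` (with a `# N=` header) and `essential.txt` (gold list).
#' Planted essential proteins receive elevated degree (preferential
#' sampling), co-expressed and co-annotated neighborhoods (high edge
#' weights), and high ortholog counts; background proteins get uncorrelated
#' expression, shallow scattered annotations and low ortholog counts.
#'
#' @param config A [synthetic_config].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the in-memory
#'   `bundle` (edges, expression, dag, annotations, orthology, gold list).
#' @export
generate_bundle <- function(config = synthetic_config(), dir) {
  bundle <- generate_bundle_data(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    ppi = file.path(dir, "ppi.tsv"),
    expression = file.path(dir, "expression.tsv"),
    obo = file.path(dir, "go.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    orthology = file.path(dir, "orthology.tsv"),
    gold = file.path(dir, "essential.txt"),
    manifest = file.path(dir, "manifest.json")
  )
  writeLines(c("# synthetic PPI edge list",
               sprintf("%s\t%s", bundle$edges$u, bundle$edges$v)),
             paths$ppi)
  expr_lines <- vapply(seq_len(nrow(bundle$expression)), function(i) {
    paste(c(rownames(bundle$expression)[[i]],
            sprintf("%.6f", bundle$expression[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("protein", sprintf("t%02d", seq_len(config$m_samples))),
                     collapse = "\t"),
               expr_lines), paths$expression)
  write_obo(bundle$dag, paths$obo)
  write_gaf(bundle$annotations, paths$gaf)
  writeLines(c(sprintf("# N=%d", bundle$orthology$N),
               sprintf("%s\t%d", names(bundle$orthology$n),
                       bundle$orthology$n)),
             paths$orthology)
  writeLines(bundle$essential, paths$gold)
  jsonlite::write_json(
    list(generator = "imepp::generate_bundle",
         config = unclass(bundle$config),
         files = lapply(paths[setdiff(names(paths), "manifest")], basename)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, bundle = bundle))
}

# minimal OBO 1.2 writer for synthetic ontologies
write_obo <- function(dag, path) {
  ns_map <- c(BP = "biological_process", MF = "molecular_function",
              CC = "cellular_component")
  out <- c("format-version: 1.2", "ontology: synthetic")
  for (tm in dag$terms) {
    out <- c(out, "", "[Term]", paste0("id: ", tm),
             paste0("name: synthetic term ", tm),
             paste0("namespace: ", ns_map[[dag$aspect[[tm]]]]))
    ps <- dag$parents[[tm]]
    ty <- dag$types[[tm]]
    for (i in seq_along(ps)) {
      out <- c(out, if (ty[[i]] == "is_a") paste0("is_a: ", ps[[i]])
               else paste0("relationship: part_of ", ps[[i]]))
    }
  }
  writeLines(out, path)
}

# minimal GAF 2.2 writer (17 columns, IEA evidence)
write_gaf <- function(annotations, path) {
  rows <- character(0)
  for (prot in names(annotations)) {
    for (tm in annotations[[prot]]) {
      rows <- c(rows, paste(c("SYN", prot, prot, "", tm, "SYN:0000001",
                              "IEA", "", "P", "", "", "protein",
                              "taxon:0", "20240101", "SYN", "", ""),
                            collapse = "\t"))
    }
  }
  writeLines(c("!gaf-version: 2.2", rows), path)
}

#' Fixed six-protein worked example
#'
#' A hand-computable bundle used in the documentation and regression tests:
#' six proteins, a four-term ontology, four expression sampling points and a
#' ten-species orthology table. All pairwise PCC, semantic similarity,
#' edge-weight and influence-score values can be verified by hand.
#'
#' @return A list with `edges`, `expression`, `dag`, `annotations`,
#'   `orthology`, `gold` and a prebuilt `pin`.
#' @export
generate_toy_example <- function() {
  dag <- go_dag(
    terms = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
    parents = list("GO:0000001" = character(0),
                   "GO:0000002" = "GO:0000001",
                   "GO:0000003" = "GO:0000001",
                   "GO:0000004" = "GO:0000002")
  )
  expression <- rbind(
    A = c(1, 2, 3, 4),
    B = c(2, 4, 6, 8),     # PCC(A,B) = 1
    C = c(4, 3, 2, 1),     # PCC(A,C) = -1 (clamped to 0)
    D = c(1, 2, 2, 3),     # PCC(A,D) = 0.9486833
    E = c(1, 3, 2, 4),     # PCC(B,E) = 0.8
    F = c(2, 2, 2, 2)      # zero variance: PCC = 0 with everything
  )
  annotations <- structure(
    list(A = "GO:0000004", B = "GO:0000004", C = "GO:0000002",
         D = "GO:0000003", E = "GO:0000004", F = "GO:0000003"),
    class = "go_annotation"
  )
  orth <- orthology(c(A = 9, B = 1, C = 8, D = 2, E = 5, F = 10), N = 10)
  edges <- data.frame(
    u = c("A", "A", "A", "B", "C", "D"),
    v = c("B", "C", "D", "E", "D", "F"),
    stringsAsFactors = FALSE
  )
  pin <- build_weighted_pin(edges, expression, annotations, dag)
  list(edges = edges, expression = expression, dag = dag,
       annotations = annotations, orthology = orth,
       gold = c("A", "C"), pin = pin)
}
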