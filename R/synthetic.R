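# Seeded generators for every input the pipeline consumes: regulatory edge
# sets with planted FFLs of known class and arity, expression matrices with
# planted dependency chains, promoter sequences with planted motif sites,
# and annotation maps with a controlled pair-sharing rate. All generators
# are pure functions of their specification plus seed (R's default
# Mersenne-Twister generator).

#' Simulation specification for a synthetic regulome
#'
#' @param n_tf,n_mirna,n_gene node counts (ids `TF1..`, `miR1..`, `g1..`).
#' @param background_density named numeric vector of per-relation edge
#'   probabilities over the five relation kinds (missing kinds default 0).
#' @param planted named integer vector of FFLs to plant, names of the form
#'   `"<class>/<arity>"`, e.g. `c("TF-FFL/3" = 5, "composite-FFL/4" = 2)`.
#' @param seed integer seed.
#' @return list of class `regulome_sim_spec`.
#' @export
regulome_sim_spec <- function(n_tf = 10L, n_mirna = 10L, n_gene = 20L,
                              background_density = c(), planted = c(), seed = 1L) {
  dens <- setNames(rep(0, length(RELATIONS)), RELATIONS)
  if (length(background_density)) {
    bad <- setdiff(names(background_density), RELATIONS)
    if (length(bad)) stop("unknown relation(s) in background_density: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    dens[names(background_density)] <- background_density
  }
  if (any(dens < 0 | dens > 1)) stop("densities must lie in [0, 1]", call. = FALSE)
  if (length(planted)) {
    ok <- grepl("^(TF-FFL|miRNA-FFL|composite-FFL)/(3|4)$", names(planted))
    if (!all(ok)) stop("planted names must be '<class>/<arity>' like 'TF-FFL/3'",
                       call. = FALSE)
    if (any(planted < 0)) stop("planted counts must be >= 0", call. = FALSE)
  }
  structure(list(n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
                 n_gene = as.integer(n_gene), background_density = dens,
                 planted = planted, seed = as.integer(seed)),
            class = "regulome_sim_spec")
}

#' Generate a synthetic regulome with planted FFLs
#'
#' Plants each requested FFL by inserting its required edges - each planted
#' FFL takes its own (TF, miRNA) pair so planted classes cannot collide -
#' then adds background edges per relation density without ever deleting a
#' planted edge. For 4-node plants the template is the two required
#' regulator->gene edges plus exactly one optional edge chosen at random.
#' Background edges may create incidental FFLs; the truth records planted
#' ones only.
#'
#' @param spec a [regulome_sim_spec()].
#' @return list with `store` (an [edge_store()]) and `truth` (list: `ffls`
#'   data frame of planted descriptors, `edges` planted edge data frame).
#' @export
gen_regulome <- function(spec) {
  stopifnot(inherits(spec, "regulome_sim_spec"))
  tfs <- paste0("TF", seq_len(spec$n_tf))
  mirnas <- paste0("miR", seq_len(spec$n_mirna))
  genes <- paste0("g", seq_len(spec$n_gene))
  catalog <- node_catalog(genes, mirnas, tfs)
  n_plant <- sum(spec$planted)
  if (n_plant > spec$n_tf * spec$n_mirna)
    stop("not enough (TF, miRNA) pairs to host the requested plants", call. = FALSE)
  # each plant gets dedicated target genes so closed-world recovery is exact
  arity_of <- function(slot) strsplit(slot, "/", fixed = TRUE)[[1L]][2L]
  gene_need <- sum(vapply(names(spec$planted), function(s)
    spec$planted[[s]] * (if (arity_of(s) == "4") 2L else 1L), numeric(1)))
  if (gene_need > spec$n_gene)
    stop("not enough genes to host the requested plants", call. = FALSE)
  withr_seed(spec$seed, {
    pair_idx <- sample.int(spec$n_tf * spec$n_mirna, n_plant)
    pair_tf <- tfs[(pair_idx - 1L) %/% spec$n_mirna + 1L]
    pair_mir <- mirnas[(pair_idx - 1L) %% spec$n_mirna + 1L]
    gene_pool <- sample(genes, gene_need)
    planted_edges <- list()
    planted_ffls <- list()
    pi_ <- 0L
    add <- function(source, target, relation)
      planted_edges[[length(planted_edges) + 1L]] <<-
        data.frame(source = source, target = target, relation = relation)
    for (slot in names(spec$planted)) {
      parts <- strsplit(slot, "/", fixed = TRUE)[[1L]]
      cls <- parts[1L]; arity <- parts[2L]
      for (r in seq_len(spec$planted[[slot]])) {
        pi_ <- pi_ + 1L
        tf <- pair_tf[pi_]; mir <- pair_mir[pi_]
        if (cls %in% c("TF-FFL", "composite-FFL")) add(tf, mir, "TF-miRNA")
        if (cls %in% c("miRNA-FFL", "composite-FFL")) add(mir, tf, "miRNA-TF")
        if (arity == "3") {
          g <- gene_pool[1L]; gene_pool <- gene_pool[-1L]
          add(tf, g, "TF-gene"); add(mir, g, "miRNA-gene")
          members <- g
        } else {
          gp <- sort(gene_pool[1:2]); gene_pool <- gene_pool[-(1:2)]
          add(gp[1L], gp[2L], "gene-gene")
          add(tf, gp[1L], "TF-gene"); add(mir, gp[2L], "miRNA-gene")
          # exactly one optional edge: TF->g2 or miRNA->g1
          if (runif(1) < 0.5) add(tf, gp[2L], "TF-gene") else add(mir, gp[1L], "miRNA-gene")
          members <- paste(gp, collapse = "|")
        }
        planted_ffls[[pi_]] <- data.frame(
          tf = tf, mirna = mir, ffl_class = cls,
          arity = paste0(arity, "-node"), members = members,
          stringsAsFactors = FALSE)
      }
    }
    bg <- list()
    pools <- list(
      "TF-gene" = expand.grid(source = tfs, target = genes, stringsAsFactors = FALSE),
      "TF-miRNA" = expand.grid(source = tfs, target = mirnas, stringsAsFactors = FALSE),
      "miRNA-gene" = expand.grid(source = mirnas, target = genes, stringsAsFactors = FALSE),
      "miRNA-TF" = expand.grid(source = mirnas, target = tfs, stringsAsFactors = FALSE),
      "gene-gene" = if (spec$n_gene >= 2L) {
        cmb <- t(combn(genes, 2L))
        data.frame(source = cmb[, 1L], target = cmb[, 2L], stringsAsFactors = FALSE)
      } else NULL)
    for (rel in RELATIONS) {
      dens <- spec$background_density[[rel]]
      pool <- pools[[rel]]
      if (dens <= 0 || is.null(pool) || nrow(pool) == 0L) next
      take <- runif(nrow(pool)) < dens
      if (any(take))
        bg[[length(bg) + 1L]] <- data.frame(pool[take, , drop = FALSE], relation = rel)
    }
    planted <- if (length(planted_edges)) do.call(rbind, planted_edges) else empty_edge_frame()[, 1:3]
    all_edges <- rbind(planted, if (length(bg)) do.call(rbind, bg))
    truth_ffls <- if (length(planted_ffls)) do.call(rbind, planted_ffls) else
      data.frame(tf = character(0), mirna = character(0), ffl_class = character(0),
                 arity = character(0), members = character(0), stringsAsFactors = FALSE)
    list(store = edge_store(all_edges, catalog),
         truth = list(ffls = truth_ffls, edges = unique(planted)))
  })
}

#' Generate an expression matrix with planted dependency chains
#'
#' Root genes of the dependency forest are standard normal; each child is
#' its parent plus Gaussian noise, so mutual information decays along a
#' chain (the data-processing inequality of the generative model).
#' Independent standard-normal genes are appended up to `n_genes`.
#'
#' @param dependency_edges two-column matrix/data frame (parent, child);
#'   must form a forest.
#' @param n_genes total genes (>= number of genes named in the forest);
#'   extra genes (`ind1..`) are independent.
#' @param n_samples number of samples.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return numeric matrix genes x samples.
#' @export
gen_expression <- function(dependency_edges, n_genes = NULL, n_samples = 200L,
                           noise_sd = 0.5, seed = 1L) {
  dep <- if (is.null(dependency_edges) || NROW(dependency_edges) == 0L)
    data.frame(parent = character(0), child = character(0))
  else data.frame(parent = as.character(as.matrix(dependency_edges)[, 1L]),
                  child = as.character(as.matrix(dependency_edges)[, 2L]),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(dep$child))
    stop("dependency edges must form a forest (unique parents)", call. = FALSE)
  ids <- unique(c(dep$parent, dep$child))
  if (nrow(dep)) {
    g <- igraph::graph_from_data_frame(dep, directed = TRUE)
    if (!igraph::is_acyclic(g)) stop("dependency edges contain a cycle", call. = FALSE)
  }
  n_extra <- if (is.null(n_genes)) 0L else n_genes - length(ids)
  if (n_extra < 0L) stop("n_genes smaller than the dependency forest", call. = FALSE)
  withr_seed(seed, {
    vals <- list()
    remaining <- ids
    parent_of <- setNames(dep$parent, dep$child)
    while (length(remaining)) {
      ready <- remaining[vapply(remaining, function(id) {
        p <- parent_of[id]
        is.na(p) || p %in% names(vals)
      }, logical(1))]
      for (id in ready) {
        p <- parent_of[id]
        vals[[id]] <- if (is.na(p)) rnorm(n_samples)
                      else vals[[p]] + rnorm(n_samples, sd = noise_sd)
      }
      remaining <- setdiff(remaining, ready)
    }
    extra <- if (n_extra > 0L)
      setNames(lapply(seq_len(n_extra), function(i) rnorm(n_samples)),
               paste0("ind", seq_len(n_extra)))
    else NULL
    m <- do.call(rbind, c(vals, extra))
    colnames(m) <- paste0("s", seq_len(n_samples))
    m
  })
}

#' Generate promoter records with planted motif sites
#'
#' Background sequence is i.i.d. uniform over A/C/G/T; planted records carry
#' the PWM consensus at the stated offset.
#'
#' @param pwm_ a [pwm()] whose consensus is planted.
#' @param n_background number of pure-background promoters (`bg1..`,
#'   species `"hsa"`).
#' @param plants data frame with columns `node`, `species`, `offset`
#'   (0-based plant position), or NULL.
#' @param length_ promoter length (default 2000, the -1500/+500 window).
#' @param seed integer seed.
#' @return list of [promoter_record()] objects.
#' @export
gen_promoters <- function(pwm_, n_background = 0L, plants = NULL, length_ = 2000L,
                          seed = 1L) {
  if (!is.null(plants) && nrow(plants)) {
    if (any(plants$offset < 0L | plants$offset + pwm_$length > length_))
      stop("plant offset out of range for the promoter length", call. = FALSE)
  }
  cons <- pwm_consensus(pwm_)
  withr_seed(seed, {
    rand_seq <- function() paste(sample(BASES, length_, replace = TRUE), collapse = "")
    out <- list()
    if (n_background > 0L) {
      for (i in seq_len(n_background))
        out[[length(out) + 1L]] <- promoter_record(paste0("bg", i), "hsa", rand_seq())
    }
    if (!is.null(plants) && nrow(plants)) {
      for (i in seq_len(nrow(plants))) {
        s <- rand_seq()
        off <- plants$offset[i]
        s <- paste0(substr(s, 1L, off), cons,
                    substr(s, off + pwm_$length + 1L, length_))
        out[[length(out) + 1L]] <- promoter_record(plants$node[i], plants$species[i], s)
      }
    }
    out
  })
}

#' Generate an annotation map with a controlled pair-sharing rate
#'
#' Every id starts with its own private term; each supplied pair then
#' receives a common term with probability `sharing_rate` (rate 0 means no
#' designated pair shares; rate 1 means all do).
#'
#' @param ids character identifiers.
#' @param n_terms size of the shared-term pool.
#' @param sharing_rate probability in \[0, 1\] that a designated pair shares.
#' @param pairs two-column matrix/data frame of designated id pairs (may be
#'   NULL).
#' @param seed integer seed.
#' @return named list: id -> character vector of terms.
#' @export
gen_annotations <- function(ids, n_terms = 50L, sharing_rate = 0, pairs = NULL,
                            seed = 1L) {
  stopifnot(sharing_rate >= 0, sharing_rate <= 1)
  ann <- setNames(lapply(seq_along(ids), function(i) paste0("private_", ids[i])), ids)
  withr_seed(seed, {
    if (!is.null(pairs) && NROW(pairs)) {
      pairs <- as.matrix(pairs)
      share <- runif(nrow(pairs)) < sharing_rate
      for (i in which(share)) {
        term <- paste0("T", sample.int(n_terms, 1L), "_pair", i)
        ann[[pairs[i, 1L]]] <- c(ann[[pairs[i, 1L]]], term)
        ann[[pairs[i, 2L]]] <- c(ann[[pairs[i, 2L]]], term)
      }
    }
    ann
  })
}
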