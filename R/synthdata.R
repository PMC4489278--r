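# Seeded generators of toy data sets with planted functional modules:
# the statistical structure the pipeline assumes (co-functional modules,
# module-correlated expression and evidence layers, annotations derived
# from modules, ortholog maps), at a scale where every stage runs in
# seconds.  Every generator is a pure function of (spec, seed).

#' Specification for synthetic fixtures
#'
#' @param n_genes total number of genes (default 300).
#' @param n_modules number of planted functional modules (default 10).
#' @param module_size genes per module (default 20;
#'   `n_modules * module_size <= n_genes`, remaining genes are
#'   background).
#' @param p_in,p_out within-module and background edge probabilities
#'   (defaults 0.3 and 0.01; `p_in > p_out` for an informative fixture).
#' @param n_samples number of expression samples (default 28: two per
#'   default spatiotemporal context).
#' @param noise_sd standard deviation of the Gaussian expression noise
#'   around the module profile (default 0.2, in BPKM-like units).
#' @param seed integer RNG seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 300, n_modules = 10, module_size = 20,
                       p_in = 0.3, p_out = 0.01, n_samples = 28,
                       noise_sd = 0.2, seed = 1) {
  stopifnot(n_genes >= 2, n_modules >= 1, module_size >= 2,
            n_modules * module_size <= n_genes,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            n_samples >= 2, noise_sd >= 0)
  structure(list(n_genes = n_genes, n_modules = n_modules,
                 module_size = module_size, p_in = p_in, p_out = p_out,
                 n_samples = n_samples, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Default spatiotemporal context list
#'
#' Four developmental stages (embryo, larvae, pupae, adult) and ten
#' tissue types, mirroring a typical insect developmental atlas.
#'
#' @return Data frame with columns `label`, `kind` (14 contexts).
#' @export
default_contexts <- function() {
  data.frame(
    label = c("EB", "LV", "PP", "AD",
              "AG", "CC", "CN", "DS", "FB", "HD", "ID", "OV", "SG", "TT"),
    kind = c(rep("stage", 4), rep("tissue", 10)),
    stringsAsFactors = FALSE)
}

.synth_genes <- function(spec) sprintf("g%04d", seq_len(spec$n_genes))

#' Module membership table for a synthetic spec
#'
#' @param spec a [synth_spec()].
#' @return Data frame (`gene`, `module`); background genes have module
#'   `NA`.
#' @export
synth_membership <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  genes <- .synth_genes(spec)
  module <- rep(NA_character_, spec$n_genes)
  idx <- seq_len(spec$n_modules * spec$module_size)
  module[idx] <- sprintf("M%02d", rep(seq_len(spec$n_modules),
                                      each = spec$module_size))
  data.frame(gene = genes, module = module, stringsAsFactors = FALSE)
}

#' Generate a network with planted modules
#'
#' Within-module gene pairs become edges with probability `p_in`, all
#' other pairs with probability `p_out`; weights are drawn uniformly
#' from (0.5, 3).
#'
#' @param spec a [synth_spec()].
#' @return List with `network` (a [gene_network()]) and `membership`
#'   (see [synth_membership()]).
#' @export
gen_modular_network <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  mem <- synth_membership(spec)
  n <- spec$n_genes
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  same <- !is.na(mem$module[ut[, 1]]) &
    mem$module[ut[, 1]] == mem$module[ut[, 2]]
  same[is.na(same)] <- FALSE
  p <- ifelse(same, spec$p_in, spec$p_out)
  .with_seed(spec$seed, {
    draw <- stats::runif(nrow(ut)) < p
    w <- stats::runif(sum(draw), 0.5, 3)
  })
  net <- gene_network(data.frame(gene_a = mem$gene[ut[draw, 1]],
                                 gene_b = mem$gene[ut[draw, 2]],
                                 weight = w, stringsAsFactors = FALSE))
  list(network = net, membership = mem)
}

#' Generate module-correlated expression
#'
#' Each module follows a latent per-sample profile; member expression is
#' the latent value plus Gaussian noise, truncated at zero.  Background
#' genes follow independent latent profiles.  Samples are assigned
#' round-robin to the context list.  Chosen modules can be silenced in
#' chosen contexts (values drawn below the expression threshold), which
#' plants spatiotemporal specificity recoverable by [build_stns()].
#'
#' @param membership a [synth_membership()] table.
#' @param spec a [synth_spec()].
#' @param contexts context data frame (`label`, `kind`); default
#'   [default_contexts()].
#' @param silenced optional data frame (`module`, `label`) of
#'   module-context combinations to silence.
#' @param threshold expression threshold that silencing must stay below
#'   (default 1).
#' @return An [expression_bundle()].
#' @export
gen_expression <- function(membership, spec, contexts = default_contexts(),
                           silenced = NULL, threshold = 1) {
  stopifnot(inherits(spec, "synth_spec"), is.data.frame(contexts),
            all(c("label", "kind") %in% names(contexts)))
  if (spec$n_samples < 2) stop("need at least 2 samples", call. = FALSE)
  genes <- membership$gene
  samples <- sprintf("s%03d", seq_len(spec$n_samples))
  sample_label <- contexts$label[(seq_len(spec$n_samples) - 1) %%
                                   nrow(contexts) + 1]
  modules <- unique(stats::na.omit(membership$module))
  .with_seed(spec$seed + 1L, {
    latent <- matrix(stats::runif(length(modules) * spec$n_samples, 2, 10),
                     nrow = length(modules),
                     dimnames = list(modules, samples))
    m <- matrix(0, length(genes), spec$n_samples,
                dimnames = list(genes, samples))
    for (i in seq_along(genes)) {
      mod <- membership$module[i]
      base <- if (is.na(mod)) stats::runif(spec$n_samples, 2, 10) else
        latent[mod, ]
      m[i, ] <- base + stats::rnorm(spec$n_samples, 0, spec$noise_sd)
    }
    if (!is.null(silenced)) {
      for (r in seq_len(nrow(silenced))) {
        g <- membership$gene[!is.na(membership$module) &
                               membership$module == silenced$module[r]]
        s <- samples[sample_label == silenced$label[r]]
        if (length(s) == 0) next
        m[g, s] <- stats::runif(length(g) * length(s), 0, 0.5 * threshold)
      }
    }
  })
  m <- pmax(m, 0)
  expression_bundle(m, data.frame(sample = samples, label = sample_label,
                                  kind = contexts$kind[match(sample_label,
                                                             contexts$label)],
                                  stringsAsFactors = FALSE))
}

#' Generate module-derived annotations
#'
#' One primary term per module containing a seeded random fraction
#' (`floor(coverage * module_size)`) of its members - the source of
#' gold-standard pairs - plus a disjoint validation term per module
#' holding the held-out members, usable as an independent validation
#' set.
#'
#' @param membership a [synth_membership()] table.
#' @param coverage fraction of each module annotated by the primary term
#'   (in (0, 1], default 0.7).
#' @param seed integer RNG seed.
#' @return An [annotation_set()] with sources `"primary"` and
#'   `"validation"`.
#' @export
gen_annotations <- function(membership, coverage = 0.7, seed = 1) {
  stopifnot(coverage > 0, coverage <= 1)
  modules <- unique(stats::na.omit(membership$module))
  genes <- list(); src <- character()
  .with_seed(seed, {
    for (mod in modules) {
      members <- membership$gene[!is.na(membership$module) &
                                   membership$module == mod]
      k <- max(1L, floor(coverage * length(members)))
      ann <- sort(sample(members, k))
      genes[[mod]] <- ann
      src[mod] <- "primary"
      held <- setdiff(members, ann)
      if (length(held) > 0) {
        genes[[paste0(mod, ".val")]] <- held
        src[paste0(mod, ".val")] <- "validation"
      }
    }
  })
  annotation_set(genes, description = names(genes), source = src)
}

#' Generate a full synthetic evidence bundle
#'
#' Produces one raw [scored_pairs()] layer per evidence type, all
#' seeded from the spec: `CX` from module-correlated expression
#' ([gen_expression()] + [infer_coexpression()]); `CC`, `DC`, `PG` and
#' `GN` from module-correlated incidence tables (documents, domains,
#' phylogenetic profiles, gene order) passed through the corresponding
#' inference operations; and one pure-noise layer (code `"HT"`) whose
#' scores are independent of the modules, for calibration sanity
#' checks.  Informative layers score within-module pairs stochastically
#' higher than background pairs.
#'
#' @param membership a [synth_membership()] table.
#' @param spec a [synth_spec()].
#' @return Named list of [scored_pairs()]:
#'   `CX`, `CC`, `PG`, `DC`, `GN`, `noise`.
#' @export
gen_evidence_bundle <- function(membership, spec) {
  stopifnot(inherits(spec, "synth_spec"))
  genes <- membership$gene
  modules <- unique(stats::na.omit(membership$module))
  members <- function(mod) genes[!is.na(membership$module) &
                                   membership$module == mod]

  cx <- infer_coexpression(gen_expression(membership, spec))

  cc <- .with_seed(spec$seed + 2L, {
    gene_docs <- stats::setNames(vector("list", length(genes)), genes)
    doc_id <- 0L
    for (mod in modules) {
      for (d in 1:6) {
        doc_id <- doc_id + 1L
        cited <- members(mod)[stats::runif(spec$module_size) < 0.7]
        for (g in cited) gene_docs[[g]] <- c(gene_docs[[g]], doc_id)
      }
    }
    for (d in 1:40) {                    # unspecific background documents
      doc_id <- doc_id + 1L
      cited <- genes[stats::runif(length(genes)) < 0.05]
      for (g in cited) gene_docs[[g]] <- c(gene_docs[[g]], doc_id)
    }
    gene_docs <- lapply(gene_docs, as.character)
    gene_docs <- gene_docs[lengths(gene_docs) > 0]
    infer_cocitation(doc_incidence(gene_docs, doc_id))
  })

  pg <- .with_seed(spec$seed + 3L, {
    n_genomes <- 20L
    prof <- matrix(stats::rbinom(length(genes) * n_genomes, 1, 0.5),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("G%02d", 1:n_genomes)))
    for (mod in modules) {
      base <- stats::rbinom(n_genomes, 1, 0.5)
      for (g in members(mod)) {
        flip <- stats::runif(n_genomes) < 0.1
        prof[g, ] <- ifelse(flip, 1 - base, base)
      }
    }
    infer_phylo_profile(profile_matrix(prof))
  })

  dc <- .with_seed(spec$seed + 4L, {
    universe <- sprintf("d%03d", 1:100)
    gd <- stats::setNames(vector("list", length(genes)), genes)
    for (mod in modules) {
      mod_dom <- sample(universe, 3)
      for (g in members(mod)) {
        own <- mod_dom[stats::runif(3) < 0.6]
        gd[[g]] <- unique(c(own, sample(universe, 1)))
      }
    }
    bg <- genes[is.na(membership$module)]
    for (g in bg) gd[[g]] <- sample(universe, sample(1:3, 1))
    infer_domain_cooccurrence(domain_table(gd, length(universe)))
  })

  gn <- .with_seed(spec$seed + 5L, {
    rows <- list()
    for (gm in 1:6) {
      present <- genes[stats::runif(length(genes)) < 0.6]
      # order genomes so that present members of a module sit contiguously
      blocks <- split(present, ifelse(is.na(membership$module[match(present,
                                                                    genes)]),
                                      paste0("bg", seq_along(present)),
                                      membership$module[match(present,
                                                              genes)]))
      ordering <- unlist(blocks[sample(names(blocks))], use.names = FALSE)
      rows[[gm]] <- data.frame(genome = sprintf("N%02d", gm),
                               gene = ordering,
                               position = seq_along(ordering),
                               stringsAsFactors = FALSE)
    }
    infer_gene_neighborhood(neighborhood_table(do.call(rbind, rows)),
                            window = 2)
  })

  noise <- .with_seed(spec$seed + 6L, {
    ut <- which(upper.tri(diag(length(genes))), arr.ind = TRUE)
    scored_pairs(genes[ut[, 1]], genes[ut[, 2]],
                 stats::runif(nrow(ut)), code = "HT")
  })

  list(CX = cx, CC = cc, PG = pg, DC = dc, GN = gn, noise = noise)
}

#' Generate an ortholog map over synthetic genes
#'
#' An identity-like one-to-one map in which a seeded fraction of genes
#' additionally receive a second target ortholog (exercising
#' many-to-many mapping paths).
#'
#' @param genes character vector of source gene ids.
#' @param dup_fraction fraction of genes with a duplicated target
#'   (default 0).
#' @param seed integer RNG seed.
#' @param suffix string appended to source ids to form target ids
#'   (default `""`: targets equal sources).
#' @return An [ortholog_map()].
#' @export
gen_orthologs <- function(genes, dup_fraction = 0, seed = 1, suffix = "") {
  stopifnot(dup_fraction >= 0, dup_fraction <= 1)
  genes <- unique(as.character(genes))
  src <- genes
  tgt <- paste0(genes, suffix)
  .with_seed(seed, {
    n_dup <- floor(dup_fraction * length(genes))
    dup <- if (n_dup > 0) sample(genes, n_dup) else character(0)
  })
  dup_tgt <- if (length(dup) > 0) paste0(dup, suffix, "_2") else character(0)
  ortholog_map(data.frame(source = c(src, dup),
                          target = c(tgt, dup_tgt),
                          stringsAsFactors = FALSE))
}

#' Calibrate and integrate an evidence bundle in one call
#'
#' Convenience wrapper over the calibration module: fits a
#' [calibrate_lls()] curve per evidence layer against the gold standard
#' (layers with insufficient gold coverage are dropped with a message),
#' converts each layer into an LLS-weighted component network with
#' [apply_calibration()], and integrates the components with
#' [integrate_weighted_sum()].
#'
#' @param evidence named list of [scored_pairs()] layers.
#' @param gold a [gold_standard()].
#' @param n_bins,min_bin_count passed to [calibrate_lls()].
#' @param params an [integration_params()].
#' @return List with `curves`, `components` (named lists) and `network`
#'   (the integrated [gene_network()]).
#' @export
build_integrated_network <- function(evidence, gold, n_bins = 10,
                                     min_bin_count = 10,
                                     params = integration_params()) {
  stopifnot(is.list(evidence), length(evidence) >= 1)
  curves <- list(); components <- list()
  for (nm in names(evidence)) {
    curve <- tryCatch(calibrate_lls(evidence[[nm]], gold, n_bins = n_bins,
                                    min_bin_count = min_bin_count),
                      error = function(e) NULL)
    if (is.null(curve)) {
      message("layer '", nm, "' dropped: insufficient gold-standard coverage")
      next
    }
    curves[[nm]] <- curve
    components[[nm]] <- apply_calibration(evidence[[nm]], curve)
  }
  if (length(components) == 0) {
    stop("no evidence layer could be calibrated", call. = FALSE)
  }
  nonempty <- components[vapply(components, function(n) nrow(n$edges) > 0,
                                logical(1))]
  list(curves = curves, components = components,
       network = integrate_weighted_sum(nonempty, params))
}
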