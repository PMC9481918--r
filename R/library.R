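#' Construct and validate a guide library
#'
#' A guide library is a data frame with one row per guide and columns
#' `guide_id`, `gene`, `class`, `spacer`. Targeting guides carry a gene
#' symbol; non-targeting and intergenic control guides have `NA` genes.
#' Spacers are 20-nt ACGT strings, unique across the pool.
#'
#' @param guides data frame with columns `guide_id`, `gene`, `class`,
#'   `spacer`.
#' @return The validated library, classed `guide_library`.
#' @export
guide_library <- function(guides) {
  required <- c("guide_id", "gene", "class", "spacer")
  missing_cols <- setdiff(required, names(guides))
  if (length(missing_cols) > 0) {
    is_abort(paste0("library is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "isletscreen_data_error")
  }
  guides <- as.data.frame(guides)[required]
  guides$guide_id <- as.character(guides$guide_id)
  guides$gene <- as.character(guides$gene)
  guides$class <- as.character(guides$class)
  guides$spacer <- as.character(guides$spacer)

  if (anyDuplicated(guides$guide_id)) {
    dups <- unique(guides$guide_id[duplicated(guides$guide_id)])
    is_abort(paste0("duplicate guide_id(s): ",
                    paste(utils::head(dups, 5), collapse = ", ")),
             "isletscreen_data_error")
  }
  if (anyDuplicated(guides$spacer)) {
    dups <- unique(guides$spacer[duplicated(guides$spacer)])
    is_abort(paste0("duplicate spacer(s): ",
                    paste(utils::head(dups, 5), collapse = ", ")),
             "isletscreen_data_error")
  }
  bad_class <- which(!guides$class %in% GUIDE_CLASSES)
  if (length(bad_class) > 0) {
    is_abort(sprintf("unknown guide class '%s' at line %d",
                     guides$class[bad_class[1]], bad_class[1]),
             "isletscreen_data_error")
  }
  bad_spacer <- which(!grepl("^[ACGT]{20}$", guides$spacer))
  if (length(bad_spacer) > 0) {
    is_abort(sprintf("malformed spacer '%s' at line %d (need 20-nt ACGT)",
                     guides$spacer[bad_spacer[1]], bad_spacer[1]),
             "isletscreen_data_error")
  }
  targeting <- guides$class == "targeting"
  if (any(targeting & (is.na(guides$gene) | guides$gene == ""))) {
    i <- which(targeting & (is.na(guides$gene) | guides$gene == ""))[1]
    is_abort(sprintf("targeting guide '%s' (line %d) has no gene",
                     guides$guide_id[i], i),
             "isletscreen_data_error")
  }
  guides$gene[!targeting] <- NA_character_
  rownames(guides) <- NULL
  class(guides) <- c("guide_library", "data.frame")
  guides
}

#' Build a synthetic genome-wide guide library
#'
#' Emulates a Brunello-like knockout pool: `n_genes` genes with
#' `guides_per_gene` targeting guides each, plus non-targeting and
#' intergenic control guides. Spacers are drawn uniformly at random from
#' 20-mer ACGT space without replacement. At the published scale
#' (19,114 genes, 4 guides per gene, 941 non-targeting + 59 intergenic
#' controls) this yields 76,456 targeting guides — slightly more than the
#' real pool's 76,441, because the real library is not perfectly uniform
#' at four guides per gene.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene targeting guides per gene (default 4).
#' @param n_nt number of non-targeting control guides.
#' @param n_intergenic number of intergenic control guides.
#' @param seed integer seed; the same seed reproduces the same library.
#' @return A `guide_library` of `n_genes * guides_per_gene + n_nt +
#'   n_intergenic` guides.
#' @examples
#' lib <- build_library(n_genes = 5, guides_per_gene = 4, n_nt = 3,
#'                      n_intergenic = 1, seed = 1)
#' table(lib$class)
#' @export
build_library <- function(n_genes, guides_per_gene = 4, n_nt, n_intergenic,
                          seed) {
  if (!is_count1(n_genes) || !is_count1(guides_per_gene)) {
    is_abort("n_genes and guides_per_gene must be positive integers",
             "isletscreen_config_error")
  }
  if (!is.numeric(n_nt) || !is.numeric(n_intergenic) ||
      n_nt < 0 || n_intergenic < 0) {
    is_abort("n_nt and n_intergenic must be non-negative integers",
             "isletscreen_config_error")
  }
  n_targeting <- n_genes * guides_per_gene
  n_total <- n_targeting + n_nt + n_intergenic
  if (n_total > 4^20 / 2) {
    is_abort("requested more spacers than can be drawn without replacement",
             "isletscreen_config_error")
  }

  withr::with_seed(as.integer(seed), {
    spacers <- draw_unique_spacers(n_total)
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    lib <- data.frame(
      guide_id = c(
        sprintf("%s_g%d", rep(genes, each = guides_per_gene),
                rep(seq_len(guides_per_gene), times = n_genes)),
        if (n_nt > 0) sprintf("NT_%04d", seq_len(n_nt)),
        if (n_intergenic > 0) sprintf("INTERGENIC_%04d",
                                      seq_len(n_intergenic))
      ),
      gene = c(rep(genes, each = guides_per_gene),
               rep(NA_character_, n_nt + n_intergenic)),
      class = c(rep("targeting", n_targeting),
                rep("non_targeting", n_nt),
                rep("intergenic", n_intergenic)),
      spacer = spacers,
      stringsAsFactors = FALSE
    )
    guide_library(lib)
  })
}

# Uniform unique 20-mers; redraw collisions until the set is full. With the
# pool (< 10^5) tiny against 4^20 spacer space, one pass almost always
# suffices.
draw_unique_spacers <- function(n) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), 20L * k, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  spacers <- unique(draw(n))
  while (length(spacers) < n) {
    spacers <- unique(c(spacers, draw(n - length(spacers))))
  }
  spacers[seq_len(n)]
}

#' Guide ids of control (non-targeting and/or intergenic) guides
#'
#' @param library a `guide_library`.
#' @param classes which control classes to include; the gene-level statistic
#'   anchors on non-targeting guides only, matching the published pool's 941
#'   NT guides.
#' @return Character vector of guide ids.
#' @export
control_guides <- function(library, classes = "non_targeting") {
  stopifnot(inherits(library, "guide_library"))
  classes <- match.arg(classes, c("non_targeting", "intergenic"),
                       several.ok = TRUE)
  library$guide_id[library$class %in% classes]
}

#' @export
print.guide_library <- function(x, ...) {
  cat(sprintf("guide_library: %d guides (%d targeting / %d NT / %d intergenic), %d genes\n",
              nrow(x), sum(x$class == "targeting"),
              sum(x$class == "non_targeting"),
              sum(x$class == "intergenic"),
              length(unique(stats::na.omit(x$gene)))))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
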