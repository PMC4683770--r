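#' Read phased genotypes from a VCF file
#'
#' Loads a VCF (v4.x) of bi-allelic SNPs whose GT fields are all phased
#' (`a|b`). The mixed-model machinery assumes haplotypes are known, so any
#' unphased, missing or multi-allelic record is rejected with an error
#' naming the offending record.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A [phased_genotypes()] object.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # always a character matrix, even for a single record
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1L |
    nchar(fix[, "ALT"]) != 1L
  if (any(multi)) {
    w <- which(multi)[1L]
    abort(sprintf("record %s:%s is not a bi-allelic SNP",
                  fix[w, "CHROM"], fix[w, "POS"]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  bad <- array(!grepl("^[01]\\|[01]$", gt), dim = dim(gt))  # grepl drops dim
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "genotype of sample %s at %s:%s is '%s'; phased bi-allelic GT (a|b) is required",
      colnames(gt)[w[2L]], fix[w[1L], "CHROM"], fix[w[1L], "POS"], gt[w[1L], w[2L]]))
  }
  hap1 <- t(matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  hap2 <- t(matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  phased_genotypes(hap1, hap2, samples = colnames(gt),
                   chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                   id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"])
}

#' Write phased genotypes as a VCF file
#'
#' Plain-text VCF v4.2 with phased GT fields; the inverse of
#' [read_phased_vcf()].
#'
#' @param geno A [phased_genotypes()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "phased_geno"))
  gt <- matrix(paste0(t(geno$hap1), "|", t(geno$hap2)),
               nrow = ncol(geno$hap1))
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  body <- paste(geno$chrom, geno$pos, geno$id, geno$ref, geno$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype / fixed-effect table
#'
#' Delimited table whose first column is the sample identifier, second the
#' phenotype, and any further columns fixed-effect covariates. Individuals
#' with a missing phenotype are returned separately: they form the
#' validation population (the model simply drops their records).
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default tab).
#' @return List with `data` (tibble of phenotyped individuals) and
#'   `validation_ids` (identifiers with missing phenotype).
#' @export
read_phenotypes <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (ncol(df) < 2L) abort("phenotype table needs at least id and phenotype columns")
  names(df)[1:2] <- c("id", "y")
  miss <- is.na(df$y)
  list(data = df[!miss, , drop = FALSE],
       validation_ids = as.character(df$id[miss]))
}

#' Run the haplotype prediction / estimation pipeline from a config
#'
#' Executes enumerate -> code -> relate -> (predict and/or reml) from a YAML
#' configuration (or an equivalent list) and writes delimited outputs plus a
#' provenance file next to them. Identical config and seed give identical
#' outputs.
#'
#' Config fields: `vcf`, `phenotypes` (paths); one of `n_snps`,
#' `block_length`, `bed`; `model` (`"haplotype"`, `"snp"` or `"joint"`);
#' `dominance` (logical, default `TRUE`); `action` (`"reml"`, `"predict"`
#' or both); `method` (`"auto"`, `"ce"`, `"qm"`); optional `sigma2`
#' (named list, required for `predict` without `reml`); `reml_control`
#' (list passed to [greml_control()]); `out_dir`; `seed`.
#'
#' @param config Path to a YAML file, or a list with the fields above.
#' @return (Invisibly) a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  geno <- stage("read_vcf", read_phased_vcf(config$vcf))
  phen <- stage("read_phenotypes", read_phenotypes(config$phenotypes))
  train_ids <- intersect(geno$samples, phen$data$id)
  val_ids <- union(phen$validation_ids, setdiff(geno$samples, phen$data$id))
  train <- subset_individuals(geno, train_ids)
  y <- phen$data$y[match(train_ids, phen$data$id)]
  covars <- phen$data[match(train_ids, phen$data$id), -(1:2), drop = FALSE]
  X <- if (ncol(covars) > 0L) {
    stats::model.matrix(~ ., data = as.data.frame(covars))
  } else NULL

  model <- config$model %||% "haplotype"
  dominance <- config$dominance %||% TRUE
  terms <- list(); val_T <- list(); val_S <- list()
  if (model %in% c("haplotype", "joint")) {
    plan <- stage("plan_blocks", plan_blocks(
      train, n_snps = config$n_snps, block_length = config$block_length,
      bed = config$bed))
    cat0 <- stage("enumerate", enumerate_haplotypes(train, plan))
    cod <- stage("code", haplotype_coding(train, cat0))
    grm <- stage("relate", genomic_relationship(cod))
    terms <- c(terms, grm_terms(grm, prefix = "hap"))
    if (length(val_ids)) {
      cod0 <- haplotype_coding(subset_individuals(geno, val_ids), cat0)
      val_T$hap_add <- cod0$W_alpha / sqrt(grm$k_alpha)
      val_S$hap_add <- cross_relationship(cod0$W_alpha, cod$W_alpha, grm$k_alpha)
      if (!is.null(grm$D)) {
        val_T$hap_dom <- cod0$W_delta / sqrt(grm$k_delta)
        val_S$hap_dom <- cross_relationship(cod0$W_delta, cod$W_delta, grm$k_delta)
      }
    }
  }
  if (model %in% c("snp", "joint")) {
    st <- snp_stats(train)
    cod <- stage("code_snp", snp_coding(train, st))
    grm <- stage("relate_snp", genomic_relationship(cod))
    terms <- c(terms, grm_terms(grm, prefix = "snp"))
    if (length(val_ids)) {
      cod0 <- snp_coding(subset_individuals(geno, val_ids), st)
      val_T$snp_add <- cod0$W_alpha / sqrt(grm$k_alpha)
      val_S$snp_add <- cross_relationship(cod0$W_alpha, cod$W_alpha, grm$k_alpha)
      if (!is.null(grm$D)) {
        val_T$snp_dom <- cod0$W_delta / sqrt(grm$k_delta)
        val_S$snp_dom <- cross_relationship(cod0$W_delta, cod$W_delta, grm$k_delta)
      }
    }
  }
  if (!dominance) {
    keep <- !grepl("_dom$", names(terms))
    terms <- terms[keep]
    val_T <- val_T[!grepl("_dom$", names(val_T))]
    val_S <- val_S[!grepl("_dom$", names(val_S))]
  }

  action <- config$action %||% "reml"
  method <- config$method %||% "auto"
  out <- list(terms = terms)
  if ("reml" %in% action) {
    ctl <- do.call(greml_control, config$reml_control %||% list())
    fit_v <- stage("reml", greml(y, terms, X = X, method = method, control = ctl))
    out$greml <- fit_v
    readr::write_tsv(tidy(fit_v), file.path(out_dir, "variance_components.tsv"))
    hb <- heritabilities(fit_v)
    if (!is.null(hb$blocks)) {
      readr::write_tsv(hb$blocks, file.path(out_dir, "block_heritabilities.tsv"))
    }
  }
  if ("predict" %in% action) {
    sigma2 <- if (!is.null(out$greml)) out$greml$sigma2
              else unlist(config$sigma2)[names(terms)]
    sigma2_e <- if (!is.null(out$greml)) out$greml$sigma2_e
                else config$sigma2_e
    if (is.null(sigma2) || is.null(sigma2_e)) {
      abort("prediction needs variance components: run 'reml' or set `sigma2`/`sigma2_e`")
    }
    fit_p <- stage("predict", gblup(y, terms, sigma2 = sigma2,
                                    sigma2_e = sigma2_e, X = X, method = method))
    out$gblup <- fit_p
    pred <- dplyr::mutate(tidy(fit_p), population = "training")
    pred$sample <- train_ids[match(pred$sample, fit_p$samples)] %||% pred$sample
    if (length(val_ids)) {
      pv <- if (fit_p$method == "ce") {
        predict(fit_p, S01 = val_S, samples = val_ids)
      } else {
        predict(fit_p, T0 = val_T, samples = val_ids)
      }
      pred <- dplyr::bind_rows(pred, dplyr::mutate(pv, population = "validation"))
    }
    readr::write_tsv(pred, file.path(out_dir, "predictions.tsv"))
    out$predictions <- pred
  }
  prov <- list(
    config = config,
    config_hash = rlang::hash(config),
    q_training = length(train_ids), q_validation = length(val_ids),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("haplopart"))
  )
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yml"))
  invisible(out)
}
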