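#' Canonical mitochondrial gene vocabulary
#'
#' The 37 canonical metazoan mitochondrial genes plus the control region,
#' with their gene class. Names follow the lower-case convention used by
#' most annotation pipelines (`nad1`..`nad6`, `nad4L`, `cox1`..`cox3`,
#' `cytb`, `atp6`, `atp8`, `trnX` with `trnL1`/`trnL2` and `trnS1`/`trnS2`
#' disambiguation, `rrnL`, `rrnS`, `control_region`).
#'
#' @return A data frame with columns `name` and `gene_class`
#'   (`"PCG"`, `"tRNA"`, `"rRNA"`, or `"CR"`).
#' @export
#' @examples
#' table(mito_gene_vocabulary()$gene_class)
mito_gene_vocabulary <- function() {
  pcg <- c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
           "cox1", "cox2", "cox3", "cytb", "atp6", "atp8")
  trna <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
            "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
            "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
  rrna <- c("rrnL", "rrnS")
  data.frame(
    name = c(pcg, trna, rrna, "control_region"),
    gene_class = c(rep("PCG", length(pcg)), rep("tRNA", length(trna)),
                   rep("rRNA", length(rrna)), "CR"),
    stringsAsFactors = FALSE
  )
}

# synonym -> canonical lookup covering MITOS-, MitoZ- and GenBank-style names.
# All keys are stored lower-case without spaces/hyphens/underscores.
.gene_synonyms <- local({
  vocab <- mito_gene_vocabulary()$name
  syn <- c(
    # NADH dehydrogenase subunits
    nd1 = "nad1", nd2 = "nad2", nd3 = "nad3", nd4 = "nad4", nd4l = "nad4L",
    nd5 = "nad5", nd6 = "nad6",
    nadh1 = "nad1", nadh2 = "nad2", nadh3 = "nad3", nadh4 = "nad4",
    nadh4l = "nad4L", nadh5 = "nad5", nadh6 = "nad6",
    nadhdehydrogenasesubunit1 = "nad1", nadhdehydrogenasesubunit2 = "nad2",
    nadhdehydrogenasesubunit3 = "nad3", nadhdehydrogenasesubunit4 = "nad4",
    nadhdehydrogenasesubunit4l = "nad4L", nadhdehydrogenasesubunit5 = "nad5",
    nadhdehydrogenasesubunit6 = "nad6",
    # cytochrome c oxidase
    coi = "cox1", coii = "cox2", coiii = "cox3",
    co1 = "cox1", co2 = "cox2", co3 = "cox3",
    coxi = "cox1", coxii = "cox2", coxiii = "cox3",
    cytochromecoxidasesubunit1 = "cox1", cytochromecoxidasesubunit2 = "cox2",
    cytochromecoxidasesubunit3 = "cox3",
    cytochromecoxidasesubuniti = "cox1", cytochromecoxidasesubunitii = "cox2",
    cytochromecoxidasesubunitiii = "cox3",
    # cytochrome b, ATPases
    cob = "cytb", cytochromeb = "cytb", cytb = "cytb",
    atpase6 = "atp6", atpase8 = "atp8",
    atpsynthasef0subunit6 = "atp6", atpsynthasef0subunit8 = "atp8",
    # rRNAs
    rrn16 = "rrnL", rrn12 = "rrnS", "16srrna" = "rrnL", "12srrna" = "rrnS",
    "16sribosomalrna" = "rrnL", "12sribosomalrna" = "rrnS",
    lrrna = "rrnL", srrna = "rrnS", largesubunitribosomalrna = "rrnL",
    smallsubunitribosomalrna = "rrnS",
    # control region
    dloop = "control_region", controlregion = "control_region",
    cr = "control_region", "at-richregion" = "control_region",
    atrichregion = "control_region"
  )
  # tRNA synonyms: trnX(xxx) forms, tRNA-Xaa forms
  aa3 <- c(A = "ala", C = "cys", D = "asp", E = "glu", F = "phe", G = "gly",
           H = "his", I = "ile", K = "lys", M = "met", N = "asn", P = "pro",
           Q = "gln", R = "arg", T = "thr", V = "val", W = "trp", Y = "tyr")
  for (x in names(aa3)) {
    canon <- paste0("trn", x)
    syn[paste0("trna", aa3[[x]])] <- canon
    syn[tolower(canon)] <- canon
  }
  # split Leu/Ser: accept anticodon-tagged forms; L1=tag, L2=taa (UUR decoder),
  # S1=tct/gct (AGN decoder), S2=tga (UCN decoder)
  syn[c("trnl1", "trnleu1", "trnl(tag)", "trnleu(tag)", "trnleu(cun)")] <- "trnL1"
  syn[c("trnl2", "trnleu2", "trnl(taa)", "trnleu(taa)", "trnleu(uur)")] <- "trnL2"
  syn[c("trns1", "trnser1", "trns(tct)", "trns(gct)", "trnser(gct)", "trnser(agn)")] <- "trnS1"
  syn[c("trns2", "trnser2", "trns(tga)", "trnser(tga)", "trnser(ucn)")] <- "trnS2"
  # canonical names map to themselves
  syn[tolower(vocab)] <- vocab
  syn
})

#' Normalize a gene name to the canonical vocabulary
#'
#' Maps MITOS-, MitoZ- and GenBank-style gene names (e.g. `"ND5"`, `"COI"`,
#' `"tRNA-Leu(UUR)"`, `"D-loop"`) to the canonical symbols of
#' [mito_gene_vocabulary()]. Unknown names fail with an error rather than
#' guessing.
#'
#' @param name Character vector of gene names as found in annotations.
#' @return Character vector of canonical gene symbols.
#' @export
#' @examples
#' normalize_gene_name(c("ND5", "COI", "tRNA-Ser(UCN)", "D-loop"))
normalize_gene_name <- function(name) {
  key <- gsub("[ _-]", "", tolower(name))
  out <- unname(.gene_synonyms[key])
  # "tRNA-Leu(UUR)"-style names reduce to the trn... form
  retry <- is.na(out) & grepl("^trna", key)
  if (any(retry)) {
    out[retry] <- unname(.gene_synonyms[sub("^trna", "trn", key[retry])])
  }
  if (anyNA(out)) {
    bad <- unique(name[is.na(out)])
    stop("unmappable gene name(s): ", paste(sQuote(bad), collapse = ", "))
  }
  out
}

#' Gene class of a canonical gene symbol
#'
#' @param name Character vector of canonical gene symbols.
#' @return Character vector: `"PCG"`, `"tRNA"`, `"rRNA"` or `"CR"`.
#' @export
gene_class_of <- function(name) {
  vocab <- mito_gene_vocabulary()
  cls <- vocab$gene_class[match(name, vocab$name)]
  if (anyNA(cls)) {
    stop("not in the canonical gene vocabulary: ",
         paste(sQuote(unique(name[is.na(cls)])), collapse = ", "))
  }
  cls
}
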