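# Nine-way phyletic classification of orthologous gene clusters across
# chlorophyte (Chl), charophyte (KCM + ZCC, jointly "Cha") and embryophyte
# (Emb) clades, with the group-count, Venn and per-species occupancy reports.

CLADES <- c("Chl", "KCM", "ZCC", "Emb")

#' The nine phyletic group labels
#'
#' Closed vocabulary, in report order: the four mixed-clade groups first, then
#' the single-clade groups. "Cha" denotes the charophytes, the union of the
#' KCM and ZCC clades.
#'
#' @return Character vector of the nine labels.
#' @export
group_labels <- function() {
  c("Chl+Cha+Emb", "Cha+Emb", "Chl+Cha", "Chl+Emb",
    "Emb", "Cha", "ZCC", "KCM", "Chl")
}

#' Construct and validate a species taxonomy
#'
#' @param species_id Character vector of unique species identifiers.
#' @param clade Character vector of clade assignments, one of
#'   `Chl`, `KCM`, `ZCC`, `Emb` (case-sensitive controlled vocabulary).
#' @return A `species_taxonomy` data.frame with columns `species_id`, `clade`.
#' @export
species_taxonomy <- function(species_id, clade) {
  species_id <- as.character(species_id)
  clade <- as.character(clade)
  if (length(species_id) != length(clade)) stop("species_id/clade length mismatch")
  if (length(species_id) == 0L) stop("taxonomy must contain at least one species")
  if (anyDuplicated(species_id)) stop("duplicate species_id in taxonomy")
  unknown <- setdiff(unique(clade), CLADES)
  if (length(unknown)) {
    stop("unknown clade(s): ", paste(unknown, collapse = ", "),
         " (expected one of ", paste(CLADES, collapse = ", "), ")")
  }
  out <- data.frame(species_id = species_id, clade = clade,
                    stringsAsFactors = FALSE)
  class(out) <- c("species_taxonomy", "data.frame")
  out
}

#' Read a species taxonomy TSV (`species_id<TAB>clade`)
#'
#' @param path Path to a two-column headerless TSV.
#' @return A `species_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(dt) != 2L) stop("taxonomy TSV must have 2 columns")
  species_taxonomy(dt[[1L]], dt[[2L]])
}

#' Write a species taxonomy TSV
#' @param taxonomy A `species_taxonomy`.
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  fwrite(as.data.table(unclass(taxonomy)[c("species_id", "clade")]), path,
         sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

clade_lookup <- function(taxonomy) {
  stats::setNames(taxonomy$clade, taxonomy$species_id)
}

# The nine classification rules as predicates over clade presence flags.
# Mutually exclusive and exhaustive for any set drawn from the four clades;
# classify_ogc() asserts that exactly one fires.
phyletic_rules <- function() {
  list(
    "Chl+Cha+Emb" = function(chl, kcm, zcc, emb)  chl && (kcm || zcc) && emb,
    "Cha+Emb"     = function(chl, kcm, zcc, emb) !chl && (kcm || zcc) && emb,
    "Chl+Cha"     = function(chl, kcm, zcc, emb)  chl && (kcm || zcc) && !emb,
    "Chl+Emb"     = function(chl, kcm, zcc, emb)  chl && !kcm && !zcc && emb,
    "Emb"         = function(chl, kcm, zcc, emb) !chl && !kcm && !zcc && emb,
    "Cha"         = function(chl, kcm, zcc, emb) !chl &&  kcm &&  zcc && !emb,
    "ZCC"         = function(chl, kcm, zcc, emb) !chl && !kcm &&  zcc && !emb,
    "KCM"         = function(chl, kcm, zcc, emb) !chl &&  kcm && !zcc && !emb,
    "Chl"         = function(chl, kcm, zcc, emb)  chl && !kcm && !zcc && !emb
  )
}

#' Classify one OGC species set into a phyletic group
#'
#' Assigns the unique group label determined by which clades the species set
#' touches: the four mixed groups when more than one of Chl/Cha/Emb is
#' present, otherwise Emb, Chl, or — within the charophytes — Cha (both KCM
#' and ZCC present), ZCC, or KCM. The species set must contain at least two
#' species (the multi-species retention rule is applied before
#' classification).
#'
#' @param species_set Character vector of species identifiers (>= 2 distinct).
#' @param taxonomy A [species_taxonomy()].
#' @return One of [group_labels()].
#' @export
classify_ogc <- function(species_set, taxonomy) {
  species_set <- unique(as.character(species_set))
  if (length(species_set) < 2L) {
    stop("species_set must contain at least 2 distinct species")
  }
  lk <- clade_lookup(taxonomy)
  missing <- setdiff(species_set, names(lk))
  if (length(missing)) {
    stop("species not in taxonomy: ", paste(missing, collapse = ", "))
  }
  cl <- lk[species_set]
  fired <- classify_flags("Chl" %in% cl, "KCM" %in% cl,
                          "ZCC" %in% cl, "Emb" %in% cl)
  fired
}

classify_flags <- function(chl, kcm, zcc, emb) {
  rules <- phyletic_rules()
  hits <- vapply(rules, function(f) f(chl, kcm, zcc, emb), logical(1L))
  if (sum(hits) != 1L) {
    stop("phyletic rules fired ", sum(hits), " times (expected exactly 1)")
  }
  names(rules)[hits]
}

ogc_species_sets <- function(ogcs, protein_species_map) {
  lapply(ogcs, function(members) {
    sp <- protein_species_map[members]
    if (anyNA(sp)) {
      stop("protein absent from species map: ",
           paste(members[is.na(sp)], collapse = ", "))
    }
    unique(unname(sp))
  })
}

classify_ogcs <- function(ogcs, protein_species_map, taxonomy) {
  sets <- ogc_species_sets(ogcs, protein_species_map)
  vapply(sets, classify_ogc, character(1L), taxonomy = taxonomy)
}

#' Tabulate OGC groups (group-count report)
#'
#' Counts OGCs and member proteins per phyletic group, with the observed
#' maximum number of distinct species per OGC in each group. Totals over the
#' nine groups are attached as attributes `total_ogcs` and `total_proteins`
#' and equal the number of input OGCs and the sum of their member counts.
#'
#' @param ogcs List of OGCs (character vectors of protein ids).
#' @param protein_species_map Named character vector, protein id -> species id.
#' @param taxonomy A [species_taxonomy()].
#' @return data.frame with columns `group`, `max_species`, `n_proteins`,
#'   `n_ogcs`, one row per group label in fixed order.
#' @export
tabulate_groups <- function(ogcs, protein_species_map, taxonomy) {
  labels <- group_labels()
  out <- data.frame(group = labels, max_species = 0L,
                    n_proteins = 0L, n_ogcs = 0L, stringsAsFactors = FALSE)
  if (length(ogcs)) {
    sets <- ogc_species_sets(ogcs, protein_species_map)
    grp <- vapply(sets, classify_ogc, character(1L), taxonomy = taxonomy)
    nsp <- lengths(sets)
    npr <- lengths(ogcs)
    for (i in seq_along(labels)) {
      sel <- grp == labels[i]
      out$n_ogcs[i] <- sum(sel)
      out$n_proteins[i] <- sum(npr[sel])
      out$max_species[i] <- if (any(sel)) max(nsp[sel]) else 0L
    }
  }
  attr(out, "total_ogcs") <- sum(out$n_ogcs)
  attr(out, "total_proteins") <- sum(out$n_proteins)
  out
}

#' Venn regions of the three major taxonomic groups
#'
#' Maps the nine phyletic groups onto the seven regions of the
#' Chl/Cha/Emb Venn diagram. The charophyte-only region pools the Cha, ZCC
#' and KCM groups; every other region corresponds 1:1 to one group.
#'
#' @param table Output of [tabulate_groups()] (or any data.frame with
#'   `group` and `n_ogcs` columns covering the nine labels).
#' @return Named integer vector over the seven regions; regions sum to the
#'   total OGC count.
#' @export
venn_counts <- function(table) {
  cnt <- stats::setNames(table$n_ogcs, table$group)
  c("Chl+Cha+Emb" = unname(cnt["Chl+Cha+Emb"]),
    "Cha+Emb"     = unname(cnt["Cha+Emb"]),
    "Chl+Cha"     = unname(cnt["Chl+Cha"]),
    "Chl+Emb"     = unname(cnt["Chl+Emb"]),
    "Emb"         = unname(cnt["Emb"]),
    "Cha"         = unname(cnt["Cha"] + cnt["ZCC"] + cnt["KCM"]),
    "Chl"         = unname(cnt["Chl"]))
}

#' Per-species, per-group OGC occupancy
#'
#' For each species and phyletic group, the number of OGCs of that group that
#' contain at least one protein of the species (counts are OGCs, not
#' proteins).
#'
#' @inheritParams tabulate_groups
#' @return Integer matrix, rows = species (taxonomy order), columns = the
#'   nine group labels.
#' @export
species_occupancy <- function(ogcs, protein_species_map, taxonomy) {
  labels <- group_labels()
  m <- matrix(0L, nrow = nrow(taxonomy), ncol = length(labels),
              dimnames = list(taxonomy$species_id, labels))
  if (length(ogcs)) {
    sets <- ogc_species_sets(ogcs, protein_species_map)
    grp <- vapply(sets, classify_ogc, character(1L), taxonomy = taxonomy)
    for (i in seq_along(ogcs)) {
      m[sets[[i]], grp[i]] <- m[sets[[i]], grp[i]] + 1L
    }
  }
  m
}
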