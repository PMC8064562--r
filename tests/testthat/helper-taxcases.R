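# Enumerated decision-ladder cases: toy hit tables with hand-derived
# expected (rank, taxon), shared by the unit and acceptance suites.

syn6 <- read_synonym_groups()

ladder_cases <- list(
  list(name = "high single species",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 99),
                    toy_hit("Salicornia alpha", bitscore = 800, pident = 93)),
       rank = "species", taxon = "Salicornia bigelovii"),
  list(name = "high tier boundary 95",
       hits = toy_hit("Salicornia bigelovii", pident = 95),
       rank = "species", taxon = "Salicornia bigelovii"),
  list(name = "six-name synonym group, high",
       hits = rbind(toy_hit("Salicornia europea", pident = 99),
                    toy_hit("Salicornia patula", bitscore = 995, pident = 98),
                    toy_hit("Salicornia herbacea", bitscore = 992,
                            pident = 98)),
       rank = "species_group", taxon = "S. europaea complex"),
  list(name = "synonym group, medium tier",
       hits = rbind(toy_hit("Salicornia europea", pident = 92),
                    toy_hit("Salicornia maritima", bitscore = 996,
                            pident = 91)),
       rank = "species_group", taxon = "S. europaea complex"),
  list(name = "medium single species degrades to its group",
       hits = toy_hit("Salicornia persica", pident = 93),
       rank = "species_group", taxon = "S. europaea complex"),
  list(name = "medium single ungrouped species degrades to genus",
       hits = toy_hit("Salicornia bigelovii", pident = 93),
       rank = "genus", taxon = "Salicornia"),
  list(name = "two ungrouped congeners, high",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 99),
                    toy_hit("Salicornia rubra", bitscore = 999, pident = 98)),
       rank = "genus", taxon = "Salicornia"),
  list(name = "mixed-group congeners, medium",
       hits = rbind(toy_hit("Salicornia europea", pident = 92),
                    toy_hit("Salicornia rubra", bitscore = 998, pident = 92)),
       rank = "genus", taxon = "Salicornia"),
  list(name = "two genera one family, high",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 97),
                    toy_hit("Suaeda maritima", genus = "Suaeda",
                            bitscore = 997, pident = 96)),
       rank = "family", taxon = "Amaranthaceae"),
  list(name = "two genera one family, medium",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 92),
                    toy_hit("Suaeda maritima", genus = "Suaeda",
                            bitscore = 997, pident = 91)),
       rank = "family", taxon = "Amaranthaceae"),
  list(name = "low tier unanimous family",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 85),
                    toy_hit("Suaeda maritima", genus = "Suaeda",
                            bitscore = 940, pident = 84)),
       rank = "family", taxon = "Amaranthaceae"),
  list(name = "low tier, two families",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 85),
                    toy_hit("Atriplex halimus", genus = "Atriplex",
                            family = "Chenopodiaceae", bitscore = 998,
                            pident = 84)),
       rank = "unassigned", taxon = NA_character_),
  list(name = "low tier, one species only",
       hits = toy_hit("Salicornia bigelovii", pident = 88),
       rank = "family", taxon = "Amaranthaceae"),
  list(name = "high tier, two families in deviation set",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 99),
                    toy_hit("Atriplex halimus", genus = "Atriplex",
                            family = "Chenopodiaceae", bitscore = 999,
                            pident = 98)),
       rank = "unassigned", taxon = NA_character_),
  list(name = "runner-up outside the deviation window is ignored",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 99),
                    toy_hit("Salicornia rubra", bitscore = 970,
                            pident = 98)),
       rank = "species", taxon = "Salicornia bigelovii"),
  list(name = "runner-up inside the window forces genus",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 99),
                    toy_hit("Salicornia rubra", bitscore = 991,
                            pident = 98)),
       rank = "genus", taxon = "Salicornia"),
  list(name = "duplicate accessions of one species stay species-level",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 99),
                    toy_hit("Salicornia bigelovii", bitscore = 999,
                            pident = 98.5)),
       rank = "species", taxon = "Salicornia bigelovii"),
  list(name = "group plus outside congener inside window",
       hits = rbind(toy_hit("Salicornia europea", pident = 98),
                    toy_hit("Salicornia rubra", bitscore = 999,
                            pident = 97)),
       rank = "genus", taxon = "Salicornia"),
  list(name = "whole group inside window at high tier",
       hits = do.call(rbind, lapply(seq_along(names(syn6)), function(i)
         toy_hit(names(syn6)[i], bitscore = 1000 - i, pident = 99 - i / 10))),
       rank = "species_group", taxon = "S. europaea complex"),
  list(name = "three genera two families, medium",
       hits = rbind(toy_hit("Salicornia bigelovii", pident = 92),
                    toy_hit("Suaeda maritima", genus = "Suaeda",
                            bitscore = 999, pident = 91),
                    toy_hit("Atriplex halimus", genus = "Atriplex",
                            family = "Chenopodiaceae", bitscore = 998,
                            pident = 91)),
       rank = "unassigned", taxon = NA_character_)
)

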