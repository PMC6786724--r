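{
  "name": "butyrate_producers",
  "description": "Genus-level heuristic panel of dominant human gut butyrate producers: genera prevalent (>70% of individuals) in healthy guts whose representative genomes carry known butyrate-production pathways and which account for the bulk of butyrate-pathway abundance in human metagenomes. Species-level butyrogenic Eubacterium taxa (E. ventriosum, E. hallii, E. rectale) are excluded because their genus is not uniformly butyrogenic. Replace wholesale via read_taxon_panel() to match your taxonomy.",
  "genera": [
    "Anaerostipes",
    "Butyricicoccus",
    "Butyrivibrio",
    "Coprococcus",
    "Faecalibacterium",
    "Flavonifractor",
    "Odoribacter",
    "Oscillibacter",
    "Pseudoflavonifractor",
    "Roseburia",
    "Shuttleworthia",
    "Subdoligranulum"
  ]
}
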