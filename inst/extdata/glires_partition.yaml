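# Hierarchical clade partition for the Glires-like taxon set:
# levels map clade labels to member taxa; outgroups are never assignable as
# CSI carriers; candidate_clades lists the (level, label) pairs eligible for
# specificity assignment.
levels:
  grandorder:
    Glires: [Mus_musculus, Rattus_norvegicus, Rattus_rattus,
             Apodemus_speciosus, Arvicanthis_niloticus, Mesocricetus_auratus,
             Cricetulus_griseus, Peromyscus_leucopus, Microtus_ochrogaster,
             Ondatra_zibethicus, Nannospalax_galili, Rhizomys_pruinosus,
             Jaculus_jaculus, Castor_canadensis, Dipodomys_ordii,
             Ictidomys_tridecemlineatus, Marmota_marmota, Sciurus_vulgaris,
             Urocitellus_parryii, Glis_glis, Graphiurus_murinus,
             Cavia_porcellus, Chinchilla_lanigera, Octodon_degus,
             Heterocephalus_glaber, Fukomys_damarensis,
             Oryctolagus_cuniculus, Lepus_europaeus, Sylvilagus_floridanus,
             Ochotona_princeps]
    Euarchonta: [Homo_sapiens, Pan_troglodytes, Macaca_mulatta,
                 Tupaia_chinensis, Galeopterus_variegatus]
  order:
    Rodentia: [Mus_musculus, Rattus_norvegicus, Rattus_rattus,
               Apodemus_speciosus, Arvicanthis_niloticus,
               Mesocricetus_auratus, Cricetulus_griseus, Peromyscus_leucopus,
               Microtus_ochrogaster, Ondatra_zibethicus, Nannospalax_galili,
               Rhizomys_pruinosus, Jaculus_jaculus, Castor_canadensis,
               Dipodomys_ordii, Ictidomys_tridecemlineatus, Marmota_marmota,
               Sciurus_vulgaris, Urocitellus_parryii, Glis_glis,
               Graphiurus_murinus, Cavia_porcellus, Chinchilla_lanigera,
               Octodon_degus, Heterocephalus_glaber, Fukomys_damarensis]
    Lagomorpha: [Oryctolagus_cuniculus, Lepus_europaeus,
                 Sylvilagus_floridanus, Ochotona_princeps]
    Primates: [Homo_sapiens, Pan_troglodytes, Macaca_mulatta]
    Scandentia: [Tupaia_chinensis]
    Dermoptera: [Galeopterus_variegatus]
  suborder:
    Myomorpha: [Mus_musculus, Rattus_norvegicus, Rattus_rattus,
                Apodemus_speciosus, Arvicanthis_niloticus,
                Mesocricetus_auratus, Cricetulus_griseus,
                Peromyscus_leucopus, Microtus_ochrogaster,
                Ondatra_zibethicus, Nannospalax_galili, Rhizomys_pruinosus,
                Jaculus_jaculus]
    Castorimorpha: [Castor_canadensis, Dipodomys_ordii]
    Sciuromorpha: [Ictidomys_tridecemlineatus, Marmota_marmota,
                   Sciurus_vulgaris, Urocitellus_parryii, Glis_glis,
                   Graphiurus_murinus]
    Hystricomorpha: [Cavia_porcellus, Chinchilla_lanigera, Octodon_degus,
                     Heterocephalus_glaber, Fukomys_damarensis]
  superfamily:
    Muroidea: [Mus_musculus, Rattus_norvegicus, Rattus_rattus,
               Apodemus_speciosus, Arvicanthis_niloticus,
               Mesocricetus_auratus, Cricetulus_griseus, Peromyscus_leucopus,
               Microtus_ochrogaster, Ondatra_zibethicus, Nannospalax_galili,
               Rhizomys_pruinosus]
  family:
    Muridae: [Mus_musculus, Rattus_norvegicus, Rattus_rattus,
              Apodemus_speciosus, Arvicanthis_niloticus]
    Cricetidae: [Mesocricetus_auratus, Cricetulus_griseus,
                 Peromyscus_leucopus, Microtus_ochrogaster,
                 Ondatra_zibethicus]
    Spalacidae: [Nannospalax_galili, Rhizomys_pruinosus]
    Dipodoidea: [Jaculus_jaculus]
outgroups: [Homo_sapiens, Pan_troglodytes, Macaca_mulatta, Tupaia_chinensis,
            Galeopterus_variegatus]
candidate_clades:
  - {level: grandorder, label: Glires}
  - {level: order, label: Rodentia}
  - {level: order, label: Lagomorpha}
  - {level: suborder, label: Myomorpha}
  - {level: suborder, label: Castorimorpha}
  - {level: suborder, label: Sciuromorpha}
  - {level: suborder, label: Hystricomorpha}
  - {level: superfamily, label: Muroidea}
  - {level: family, label: Muridae}
  - {level: family, label: Cricetidae}
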