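# Dutch seven-drug 'essential' DGI portfolio.
# Provenance per field: see dutch_provenance.csv.
schedule:
  pharmacist_minutes: 18
  physician_minutes: 6
  hcp_cost_per_actionable: 16.39
scenarios:
  - drug: "Azathioprine"
    gene: TPMT
    initiators: 6979
    test_cost: 132
    drug_cost_soc: 248
    drug_cost_pgx: 237
    certainty: 2
    strata_file: dutch_strata.csv
  - drug: "Capecitabine"
    gene: DPYD
    initiators: 8860
    test_cost: 132
    drug_cost_soc: 1204
    drug_cost_pgx: 1158
    certainty: 1
    strata_file: dutch_strata.csv
  - drug: "Clopidogrel"
    gene: CYP2C19
    initiators: 117900
    test_cost: 132
    drug_cost_soc: 15
    drug_cost_pgx: 38
    certainty: 3
    strata_file: dutch_strata.csv
  - drug: "Fluorouracil (systemic)"
    gene: DPYD
    initiators: 6765
    test_cost: 132
    drug_cost_soc: 82
    drug_cost_pgx: 79
    certainty: 1
    strata_file: dutch_strata.csv
  - drug: "Irinotecan"
    gene: UGT1A1
    initiators: 2593
    test_cost: 66
    drug_cost_soc: 14842
    drug_cost_pgx: 14588
    certainty: 2
    strata_file: dutch_strata.csv
  - drug: "Mercaptopurine"
    gene: TPMT
    initiators: 2177
    test_cost: 132
    drug_cost_soc: 1956
    drug_cost_pgx: 1875
    certainty: 2
    strata_file: dutch_strata.csv
  - drug: "Tioguanine"
    gene: TPMT
    initiators: 2854
    test_cost: 132
    drug_cost_soc: 1088
    drug_cost_pgx: 1080
    certainty: 0
    strata_file: dutch_strata.csv
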