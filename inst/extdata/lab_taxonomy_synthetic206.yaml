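combos:
  pct_neutrophils:
  - pct_neutrophils_1
  - pct_neutrophils_2
  - pct_neutrophils_3
  - pct_neutrophils_4
  - pct_neutrophils_5
  - pct_neutrophils_6
  - pct_neutrophils_7
  alt:
  - alt_1
  - alt_2
  - alt_3
  - alt_4
  - alt_5
  - alt_6
  - alt_7
  serum_albumin:
  - serum_albumin_1
  - serum_albumin_2
  - serum_albumin_3
  - serum_albumin_4
  - serum_albumin_5
  - serum_albumin_6
  - serum_albumin_7
  ast:
  - ast_1
  - ast_2
  - ast_3
  - ast_4
  - ast_5
  - ast_6
  - ast_7
  pct_basophils:
  - pct_basophils_1
  - pct_basophils_2
  - pct_basophils_3
  - pct_basophils_4
  - pct_basophils_5
  - pct_basophils_6
  - pct_basophils_7
  bilirubin_direct:
  - bilirubin_direct_1
  - bilirubin_direct_2
  - bilirubin_direct_3
  - bilirubin_direct_4
  - bilirubin_direct_5
  - bilirubin_direct_6
  - bilirubin_direct_7
  bilirubin_indirect:
  - bilirubin_indirect_1
  - bilirubin_indirect_2
  - bilirubin_indirect_3
  - bilirubin_indirect_4
  - bilirubin_indirect_5
  - bilirubin_indirect_6
  - bilirubin_indirect_7
  alk_phos:
  - alk_phos_1
  - alk_phos_2
  - alk_phos_3
  - alk_phos_4
  - alk_phos_5
  - alk_phos_6
  - alk_phos_7
  calcium:
  - calcium_1
  - calcium_2
  - calcium_3
  - calcium_4
  - calcium_5
  - calcium_6
  - calcium_7
  pt:
  - pt_1
  - pt_2
  - pt_3
  - pt_4
  - pt_5
  - pt_6
  - pt_7
  rbc:
  - rbc_1
  - rbc_2
  - rbc_3
  - rbc_4
  - rbc_5
  - rbc_6
  - rbc_7
  rdw:
  - rdw_1
  - rdw_2
  - rdw_3
  - rdw_4
  - rdw_5
  - rdw_6
  - rdw_7
  sodium:
  - sodium_1
  - sodium_2
  - sodium_3
  - sodium_4
  - sodium_5
  - sodium_6
  - sodium_7
  hba1c:
  - hba1c_1
  - hba1c_2
  - hba1c_3
  - hba1c_4
  - hba1c_5
  - hba1c_6
  - hba1c_7
  potassium:
  - potassium_1
  - potassium_2
  - potassium_3
  - potassium_4
  - potassium_5
  - potassium_6
  total_protein:
  - total_protein_1
  - total_protein_2
  - total_protein_3
  - total_protein_4
  - total_protein_5
  - total_protein_6
  phosphorus:
  - phosphorus_1
  - phosphorus_2
  - phosphorus_3
  - phosphorus_4
  - phosphorus_5
  - phosphorus_6
  platelets:
  - platelets_1
  - platelets_2
  - platelets_3
  - platelets_4
  - platelets_5
  - platelets_6
  wbc:
  - wbc_1
  - wbc_2
  - wbc_3
  - wbc_4
  - wbc_5
  - wbc_6
  chloride:
  - chloride_1
  - chloride_2
  - chloride_3
  - chloride_4
  - chloride_5
  - chloride_6
  creatinine:
  - creatinine_1
  - creatinine_2
  - creatinine_3
  - creatinine_4
  - creatinine_5
  - creatinine_6
  pct_eosinophils:
  - pct_eosinophils_1
  - pct_eosinophils_2
  - pct_eosinophils_3
  - pct_eosinophils_4
  - pct_eosinophils_5
  - pct_eosinophils_6
  glucose:
  - glucose_1
  - glucose_2
  - glucose_3
  - glucose_4
  - glucose_5
  - glucose_6
  mcv:
  - mcv_1
  - mcv_2
  - mcv_3
  - mcv_4
  - mcv_5
  - mcv_6
  pct_monocytes:
  - pct_monocytes_1
  - pct_monocytes_2
  - pct_monocytes_3
  - pct_monocytes_4
  - pct_monocytes_5
  - pct_monocytes_6
  hemoglobin:
  - hemoglobin_1
  - hemoglobin_2
  - hemoglobin_3
  - hemoglobin_4
  - hemoglobin_5
  - hemoglobin_6
  mch:
  - mch_1
  - mch_2
  - mch_3
  - mch_4
  - mch_5
  - mch_6
  hematocrit:
  - hematocrit_1
  - hematocrit_2
  - hematocrit_3
  - hematocrit_4
  - hematocrit_5
  - hematocrit_6
  pct_lymphocytes:
  - pct_lymphocytes_1
  - pct_lymphocytes_2
  - pct_lymphocytes_3
  - pct_lymphocytes_4
  - pct_lymphocytes_5
  - pct_lymphocytes_6
  magnesium:
  - magnesium_1
  - magnesium_2
  - magnesium_3
  - magnesium_4
  - magnesium_5
  - magnesium_6
  abs_neutrophils:
  - abs_neutrophils_1
  - abs_neutrophils_2
  - abs_neutrophils_3
  - abs_neutrophils_4
  - abs_neutrophils_5
  - abs_neutrophils_6
  abs_basophils:
  - abs_basophils_1
  - abs_basophils_2
  - abs_basophils_3
  - abs_basophils_4
  - abs_basophils_5
  - abs_basophils_6
strategies:
  g1:
    white blood cell group:
    - pct_neutrophils
    - pct_basophils
    - wbc
    - pct_eosinophils
    - pct_monocytes
    - pct_lymphocytes
    - abs_neutrophils
    - abs_basophils
    red blood cell group:
    - rbc
    - rdw
    - platelets
    - hemoglobin
    - mch
    - hematocrit
    - mcv
    liver function group:
    - alt
    - serum_albumin
    - ast
    - bilirubin_direct
    - bilirubin_indirect
    - alk_phos
    - pt
    - total_protein
    kidney group:
    - calcium
    - sodium
    - potassium
    - phosphorus
    - chloride
    - magnesium
    - creatinine
    diabetes group:
    - hba1c
    - glucose
  g2:
    comp1:
    - pct_neutrophils
    - alt
    - ast
    - bilirubin_direct
    - bilirubin_indirect
    - alk_phos
    - calcium
    - pt
    - platelets
    - phosphorus
    - wbc
    - creatinine
    - pct_eosinophils
    - glucose
    - mcv
    - pct_monocytes
    - mch
    - hematocrit
    - pct_lymphocytes
    - abs_neutrophils
    comp2:
    - sodium
    - chloride
    - potassium
    - total_protein
    comp3:
    - serum_albumin
    - pct_basophils
    - rbc
    - rdw
    - hba1c
    - hemoglobin
    - magnesium
    - abs_basophils
  g3:
    comp1:
    - pct_neutrophils
    - creatinine
    comp2:
    - alt
    - pct_eosinophils
    - phosphorus
    - alk_phos
    comp3:
    - ast
    - bilirubin_direct
    comp4:
    - pt
    - glucose
    comp5:
    - sodium
    - chloride
    - potassium
    comp6:
    - mcv
    - mch
    comp7:
    - serum_albumin
    - pct_basophils
    - bilirubin_indirect
    - calcium
    - rbc
    - rdw
    - hba1c
    - total_protein
    - platelets
    - wbc
    - pct_monocytes
    - hemoglobin
    - hematocrit
    - pct_lymphocytes
    - magnesium
    - abs_neutrophils
    - abs_basophils
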