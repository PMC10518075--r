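"external_id","variable_id"
"f23400","XXL_VLDL_P"
"f23402","XXL_VLDL_L"
"f23404","XXL_VLDL_PL"
"f23406","XXL_VLDL_C"
"f23408","XXL_VLDL_CE"
"f23410","XXL_VLDL_FC"
"f23412","XXL_VLDL_TG"
"f23414","XXL_VLDL_PL_pct"
"f23416","XXL_VLDL_C_pct"
"f23418","XXL_VLDL_CE_pct"
"f23420","XXL_VLDL_FC_pct"
"f23422","XXL_VLDL_TG_pct"
"f23424","XL_VLDL_P"
"f23426","XL_VLDL_L"
"f23428","XL_VLDL_PL"
"f23430","XL_VLDL_C"
"f23432","XL_VLDL_CE"
"f23434","XL_VLDL_FC"
"f23436","XL_VLDL_TG"
"f23438","XL_VLDL_PL_pct"
"f23440","XL_VLDL_C_pct"
"f23442","XL_VLDL_CE_pct"
"f23444","XL_VLDL_FC_pct"
"f23446","XL_VLDL_TG_pct"
"f23448","VLDL_size"
"f23450","LDL_size"
"f23452","HDL_size"
"f23454","ApoA1"
"f23456","ApoB"
"f23458","ApoB_by_ApoA1"
"f23460","Total_P"
"f23462","VLDL_P"
"f23464","LDL_P"
"f23466","HDL_P"
"f23468","Total_C"
"f23470","non_HDL_C"
"f23472","Remnant_C"
"f23474","VLDL_C"
"f23476","Clinical_LDL_C"
"f23478","LDL_C"
"f23480","HDL_C"
"f23482","HDL2_C"
"f23484","Total_CE"
"f23486","VLDL_CE"
"f23488","LDL_CE"
"f23490","HDL_CE"
"f23492","Total_FC"
"f23494","VLDL_FC"
"f23496","LDL_FC"
"f23498","HDL_FC"
"f23500","Total_TG"
"f23502","VLDL_TG"
"f23504","LDL_TG"
"f23506","HDL_TG"
"f23508","Total_PL"
"f23510","VLDL_PL"
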