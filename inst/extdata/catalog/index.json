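["Autophagy_Xu.json","Autophagy_ChenM.json","Autophagy_Wang.json","Autophagy_ChenH.json","VEGF_Hu.json","CellCycle_Lundberg.json","CellCycle_Davoli.json","platinumResistanceSign.json","CIN_Carter.json","HRDS_Lu.json","DNArep_Kang.json","EMT_Miow.json","EMT_Mak.json","EMT_Cheng.synthetic-genes.json","Matrisome_Yuzhalin.json","ECM_Chakravarthy.synthetic-genes.json","CIS_Robertson.json","Ferroptosis_Ye.json","Ferroptosis_Liang.json","Ferroptosis_Liu.json","Ferroptosis_Li.json","Hypoxia_Buffa.synthetic-genes.json","ImmunoScore_Hao.json","ImmunoScore_Roh.json","IPS_Charoentong.synthetic-genes.json","ImmuneCyt_Rooney.json","IFN_Ayers.json","ExpandedImmune_Ayers.json","Tinflam_Ayers.json","TLS_Cabrita.json","ImmuneCyt_Davoli.json","Chemokines_Messina.json","PassON_Du.json","IPRES_Hugo.json","IPSOV.json","LipidMetabolism_Zheng.json","Glycolysis_Zhang.json","Glycolysis_Xu.json","MitoticIndex_Yang.json","ConsensusOV_Chen.synthetic-genes.json","Pyroptosis_Ye.json","Pyroptosis_Shao.json","Pyroptosis_Lin.json","Pyroptosis_Li.json","StemCellCD49f_Smith.json","ASC_Smith.json","ISC_MerlosSuarez.json"]
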