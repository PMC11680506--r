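# Bundled cell-state gene signatures (mouse gene symbols, as curated
# from the oligodendrocyte-lineage / glial reactivity literature).
# Lists are stored as curated; duplicated symbols are collapsed at load
# time and the duplication is recorded. "lcn2" is kept lowercase as
# curated; the case-insensitive matcher resolves it against Lcn2.
ol_genesis:
  description: genes enriched in cells primed for oligodendrocyte differentiation
  genes: [Ptprz1, Qk, Itpr2, Gpr17, Fyn, Tcf7l2]
ol_maturation:
  description: genes enriched in mature oligodendrocytes
  genes: [Mog, Mag, Cnp, Plp1, Myrf, Egr2, Fos, Fosb, Klk6, Ptgds, Car2,
          Grm3, Npsr1, Jph4, Aspa, Msmo1, Sqle, Hmgcs1, Idi1, Opalin, Trf]
reactive_astrocyte:
  description: genes enriched in reactive over homeostatic astrocytes
  genes: [Serpina3n, C3, Emp1, Gfap, Ggta1, H2-T23, Cd109, Hspb1, lcn2]
reactive_microglia:
  description: genes enriched in reactive over homeostatic microglia
  genes: [Lpl, Cst7, Ptprc, Trem2, Lgals3, Axl, Lyz2, Clec7a, Spp1, Cst7, Apoe]
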