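microglia	canonical mouse microglia markers	Cx3cr1	P2ry12	Tmem119	Hexb	Csf1r	Itgam	Trem2	Aif1
astrocyte	canonical mouse astrocyte markers	Gfap	Aqp4	Slc1a3	Aldoc	Gja1	S100b	Sox9
oligodendrocyte	canonical mouse oligodendrocyte markers	Plp1	Mbp	Mog	Mag	Cnp	Sox10
OPC	canonical mouse oligodendrocyte-precursor markers	Pdgfra	Cspg4	Olig1	Olig2	Sox10
neuron	canonical mouse neuron markers	Rbfox3	Snap25	Syt1	Meg3	Tubb3
endothelial	canonical mouse brain endothelial markers	Cldn5	Pecam1	Flt1	Slco1a4
pericyte	canonical mouse pericyte markers	Pdgfrb	Rgs5	Kcnj8	Anpep
T_cell	canonical mouse T-cell markers	Cd3e	Cd3d	Cd3g	Cd2	Cd8a	Cd4	Lck
dendritic	canonical mouse dendritic-cell markers	Cd74	H2-Aa	H2-Ab1	Itgax	Flt3
ependymal	canonical mouse ependymal markers	Foxj1	Ttr	Hdc	Ccdc153
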