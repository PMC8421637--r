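node_id	subnetwork
n1	default-mode
n2	default-mode
n3	default-mode
n4	default-mode
n5	occipital
n6	occipital
n7	occipital
n8	cingulo-opercular
n9	cingulo-opercular
n10	cingulo-opercular
n11	cingulo-opercular
n12	fronto-parietal
n13	fronto-parietal
n14	fronto-parietal
n15	sensorimotor
n16	sensorimotor
n17	sensorimotor
n18	sensorimotor
n19	cerebellar
n20	cerebellar
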