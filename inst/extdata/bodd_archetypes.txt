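# boddr archetype database v1
RECORD c.ethane_p1.C1 57e5df9d2ed8dfb9 C 0.01
GRAPH V[(0|0|481|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|480|1|1)};(1|108|108|1|1){(0|0|481|0|1)};(1|109|109|1|1){(0|0|481|0|1)};(1|109|109|1|1){(0|0|481|0|1)};(1|154|480|1|1){(0|0|481|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)};(2|216|0|2|1){(1|154|480|1|1)};(2|216|0|2|1){(1|154|480|1|1)};(2|216|0|2|1){(1|154|480|1|1)}]E[(0|0|481|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|480|1|1)}~(1|108|108|1|1){(0|0|481|0|1)};(0|0|481|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|480|1|1)}~(1|109|109|1|1){(0|0|481|0|1)};(0|0|481|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|480|1|1)}~(1|109|109|1|1){(0|0|481|0|1)};(0|0|481|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|480|1|1)}~(1|154|480|1|1){(0|0|481|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)};(1|154|480|1|1){(0|0|481|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)}~(2|216|0|2|1){(1|154|480|1|1)};(1|154|480|1|1){(0|0|481|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)}~(2|216|0|2|1){(1|154|480|1|1)};(1|154|480|1|1){(0|0|481|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)}~(2|216|0|2|1){(1|154|480|1|1)}]
COLORS [["0:481"],["108:108","109:109","109:109","154:480"],["216:0","216:0","216:0"]]
TEMPLATE BEDE * @C 0.52 0.18 1 1.4
TEMPLATE BEDE * @H 0.37 0.12 1.1 1.5
END
RECORD c.ethane_p1.C2 74e279015d9bdb00 C 0.01
GRAPH V[(0|0|480|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|481|1|1)};(1|108|108|1|1){(0|0|480|0|1)};(1|109|109|1|1){(0|0|480|0|1)};(1|109|109|1|1){(0|0|480|0|1)};(1|154|481|1|1){(0|0|480|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)};(2|216|0|2|1){(1|154|481|1|1)};(2|216|0|2|1){(1|154|481|1|1)};(2|216|0|2|1){(1|154|481|1|1)}]E[(0|0|480|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|481|1|1)}~(1|108|108|1|1){(0|0|480|0|1)};(0|0|480|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|481|1|1)}~(1|109|109|1|1){(0|0|480|0|1)};(0|0|480|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|481|1|1)}~(1|109|109|1|1){(0|0|480|0|1)};(0|0|480|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|154|481|1|1)}~(1|154|481|1|1){(0|0|480|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)};(1|154|481|1|1){(0|0|480|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)}~(2|216|0|2|1){(1|154|481|1|1)};(1|154|481|1|1){(0|0|480|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)}~(2|216|0|2|1){(1|154|481|1|1)};(1|154|481|1|1){(0|0|480|0|1),(2|216|0|2|1),(2|216|0|2|1),(2|216|0|2|1)}~(2|216|0|2|1){(1|154|481|1|1)}]
COLORS [["0:480"],["108:108","109:109","109:109","154:481"],["216:0","216:0","216:0"]]
TEMPLATE BEDE * @C 0.52 0.18 1 1.4
TEMPLATE BEDE * @H 0.37 0.12 1.1 1.5
END
RECORD c.carbonyl_p1.C1 4640622b4f4e0380 C 0.01
GRAPH V[(0|0|339|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|121|121|1|1)};(1|108|108|1|1){(0|0|339|0|1)};(1|109|109|1|1){(0|0|339|0|1)};(1|121|121|1|1){(0|0|339|0|1)}]E[(0|0|339|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|121|121|1|1)}~(1|108|108|1|1){(0|0|339|0|1)};(0|0|339|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|121|121|1|1)}~(1|109|109|1|1){(0|0|339|0|1)};(0|0|339|0|1){(1|108|108|1|1),(1|109|109|1|1),(1|121|121|1|1)}~(1|121|121|1|1){(0|0|339|0|1)}]
COLORS [["0:339"],["108:108","109:109","121:121"],[]]
TEMPLATE BEDE * @O 0.45 0.22 0.9 1.3
TEMPLATE BEDE * @H 0.37 0.12 1.1 1.5
END
RECORD o.carbonyl_p1.O1 11529d3927edc3c0 O 0.01
GRAPH V[(0|0|121|0|1){(1|121|339|1|1)};(1|121|339|1|1){(0|0|121|0|1),(2|200|0|2|1),(2|202|0|2|1)};(2|200|0|2|1){(1|121|339|1|1)};(2|202|0|2|1){(1|121|339|1|1)}]E[(0|0|121|0|1){(1|121|339|1|1)}~(1|121|339|1|1){(0|0|121|0|1),(2|200|0|2|1),(2|202|0|2|1)};(1|121|339|1|1){(0|0|121|0|1),(2|200|0|2|1),(2|202|0|2|1)}~(2|200|0|2|1){(1|121|339|1|1)};(1|121|339|1|1){(0|0|121|0|1),(2|200|0|2|1),(2|202|0|2|1)}~(2|202|0|2|1){(1|121|339|1|1)}]
COLORS [["0:121"],["121:339"],["200:0","202:0"]]
TEMPLATE BEDE * @C 0.4 0.16 0.9 1.3
TEMPLATE LONE 9 * 0.14 1 1.3 0.35 120
END
RECORD o.water_p1.O1 0c34f80d6df2d8b6 O 0.01
GRAPH V[(0|0|191|0|1){(1|95|95|1|1),(1|96|96|1|1)};(1|95|95|1|1){(0|0|191|0|1)};(1|96|96|1|1){(0|0|191|0|1)}]E[(0|0|191|0|1){(1|95|95|1|1),(1|96|96|1|1)}~(1|95|95|1|1){(0|0|191|0|1)};(0|0|191|0|1){(1|95|95|1|1),(1|96|96|1|1)}~(1|96|96|1|1){(0|0|191|0|1)}]
COLORS [["0:191"],["95:95","96:96"],[]]
TEMPLATE BEDE * @H 0.33 0.12 1 1.4
TEMPLATE LONE 2 * 0.15 1 1.3 0.35 109.5
END
RECORD c.methylamine_p1.C1 4309dc6a10c8e6a7 C 0.01
GRAPH V[(0|0|473|0|1){(1|109|109|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|147|348|1|1)};(1|109|109|1|1){(0|0|473|0|1)};(1|109|109|1|1){(0|0|473|0|1)};(1|109|109|1|1){(0|0|473|0|1)};(1|147|348|1|1){(0|0|473|0|1),(2|205|0|2|1),(2|205|0|2|1)};(2|205|0|2|1){(1|147|348|1|1)};(2|205|0|2|1){(1|147|348|1|1)}]E[(0|0|473|0|1){(1|109|109|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|147|348|1|1)}~(1|109|109|1|1){(0|0|473|0|1)};(0|0|473|0|1){(1|109|109|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|147|348|1|1)}~(1|109|109|1|1){(0|0|473|0|1)};(0|0|473|0|1){(1|109|109|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|147|348|1|1)}~(1|109|109|1|1){(0|0|473|0|1)};(0|0|473|0|1){(1|109|109|1|1),(1|109|109|1|1),(1|109|109|1|1),(1|147|348|1|1)}~(1|147|348|1|1){(0|0|473|0|1),(2|205|0|2|1),(2|205|0|2|1)};(1|147|348|1|1){(0|0|473|0|1),(2|205|0|2|1),(2|205|0|2|1)}~(2|205|0|2|1){(1|147|348|1|1)};(1|147|348|1|1){(0|0|473|0|1),(2|205|0|2|1),(2|205|0|2|1)}~(2|205|0|2|1){(1|147|348|1|1)}]
COLORS [["0:473"],["109:109","109:109","109:109","147:348"],["205:0","205:0"]]
TEMPLATE BEDE * @N 0.5 0.2 1 1.3
TEMPLATE BEDE * @H 0.37 0.12 1.1 1.5
END
RECORD n.methylamine_p1.N1 7f40041d0e6b5b39 N 0.01
GRAPH V[(0|0|348|0|1){(1|100|100|1|1),(1|101|101|1|1),(1|147|473|1|1)};(1|100|100|1|1){(0|0|348|0|1)};(1|101|101|1|1){(0|0|348|0|1)};(1|147|473|1|1){(0|0|348|0|1),(2|210|0|2|1),(2|210|0|2|1),(2|210|0|2|1)};(2|210|0|2|1){(1|147|473|1|1)};(2|210|0|2|1){(1|147|473|1|1)};(2|210|0|2|1){(1|147|473|1|1)}]E[(0|0|348|0|1){(1|100|100|1|1),(1|101|101|1|1),(1|147|473|1|1)}~(1|100|100|1|1){(0|0|348|0|1)};(0|0|348|0|1){(1|100|100|1|1),(1|101|101|1|1),(1|147|473|1|1)}~(1|101|101|1|1){(0|0|348|0|1)};(0|0|348|0|1){(1|100|100|1|1),(1|101|101|1|1),(1|147|473|1|1)}~(1|147|473|1|1){(0|0|348|0|1),(2|210|0|2|1),(2|210|0|2|1),(2|210|0|2|1)};(1|147|473|1|1){(0|0|348|0|1),(2|210|0|2|1),(2|210|0|2|1),(2|210|0|2|1)}~(2|210|0|2|1){(1|147|473|1|1)};(1|147|473|1|1){(0|0|348|0|1),(2|210|0|2|1),(2|210|0|2|1),(2|210|0|2|1)}~(2|210|0|2|1){(1|147|473|1|1)};(1|147|473|1|1){(0|0|348|0|1),(2|210|0|2|1),(2|210|0|2|1),(2|210|0|2|1)}~(2|210|0|2|1){(1|147|473|1|1)}]
COLORS [["0:348"],["100:100","101:101","147:473"],["210:0","210:0","210:0"]]
TEMPLATE BEDE * @C 0.45 0.16 1 1.3
TEMPLATE BEDE * @H 0.34 0.13 1.1 1.5
TEMPLATE LONE 1 * 0.18 1 1.3 0.38
END
RECORD o.mixed_metal_p1.O1 152530306c622026 O 0.01
GRAPH V[(0|0|200|0|1){(1|200|400|1|1)};(1|200|400|1|1){(0|0|200|0|1),(2|400|0|2|1)};(2|400|0|2|1){(1|200|400|1|1)}]E[(0|0|200|0|1){(1|200|400|1|1)}~(1|200|400|1|1){(0|0|200|0|1),(2|400|0|2|1)};(1|200|400|1|1){(0|0|200|0|1),(2|400|0|2|1)}~(2|400|0|2|1){(1|200|400|1|1)}]
COLORS [["0:200"],["200:400"],["400:0"]]
TEMPLATE BEDE * @FE 0.55 0.12 1 1.3
TEMPLATE LONE 3 * 0.12 1 1.3 0.36 109.5
END
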