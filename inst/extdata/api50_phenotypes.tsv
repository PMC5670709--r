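carbohydrate	DSM 22330	DSM 20684	JCM 16395	ATCC 19257	DSM 20450	ATCC 19435	DSM 21502	DSM 6634	DSM 20686	ATCC 43920
control	-	-	-	-	-	-	-	-	-	-
L-Arabinose	-	-	-	-	-	-	-	-	-	-
Ribose	-	+	+	-	-	+	+	-	-	-
D-xylose	-	-	-	-	-	+	-	+	-	+
D-Glucose	+	+	+	+	+	+	+	+	+	+
D-Fructose	+	+	+	+	+	+	+	+	+	+
D-Mannose	+	+	+	+	+	+	w	+	+	+
L-Sorbose	-	-	-	-	-	-	-	-	-	-
L-Rhamnose	-	-	-	-	-	-	-	-	-	-
D-Sorbitol	-	-	-	-	-	-	-	-	+	-
Amygdalin	+	+	-	-	-	w	+	+	+	-
D-Cellobiose	+	+	+	-	+	+	+	+	+	+
D-Maltose	+	+	+	-	+	+	+	+	+	+
D-Lactose	-	+	+	+	+	+	+	+	-	+
D-Melibiose	-	-	-	-	-	-	+	+	-	+
D-Sucrose	+	-	-	-	+	-	+	+	+	+
D-Trehalose	+	+	+	-	-	+	+	+	+	+
D-Raffinose	-	-	-	-	-	-	+	+	-	+
Xylitol	-	-	-	-	-	-	-	-	-	-
D-Lyxose	-	-	-	-	-	-	-	-	-	-
D-Tagatose	-	-	-	-	-	-	-	-	-	-
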