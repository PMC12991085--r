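# fepout text dialect (v1)

Plain-text record of per-window alchemical energy-difference samples, written
by `write_fepout()` and read by `parse_fepout()`.

Records, one per line, whitespace-separated:

    WINDOW <index> <lambda_start> <lambda_end> <forward|backward>
    SAMPLE <step> <delta_u_kcal_mol>
    #EQUIL_END

* `WINDOW` opens a window; all following `SAMPLE` lines belong to it until the
  next `WINDOW` header or end of file. `lambda_end - lambda_start` must equal
  plus/minus the schedule's `delta_lambda`.
* `SAMPLE` carries a step counter and one Delta-U sample in kcal/mol.
* `#EQUIL_END`, if present inside a window, marks the end of the alchemical
  equilibration span: samples before it are excluded from estimation by
  default (they are counted, never silently dropped).
* Any other line starting with `#` is a comment. Blank lines are ignored.
* Forward and backward legs may share a file or be split across files; legs
  are matched downstream by lambda pair, not by file layout.
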