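#!/usr/bin/env bash
# thin wrapper: ctt <subcommand> [options]
CLI="$(Rscript --vanilla -e 'cat(system.file("cli", "ctt.R", package = "cttrack"))')"
exec Rscript "$CLI" "$@"
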