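# Drop-in location for the deposited study data

The acceptance tests that reproduce the published per-trial results look
here for a local copy of the study's deposited trajectory data
(Dryad accession 10.5061/dryad.83bk3j9xr), converted to the package's CSV
schema:

* `trajectories.csv` — columns `trial_id,fish_id,t_s,x_cm,y_cm`, one row
  per 1 Hz sample, coordinates in the tank frame (origin top-left,
  x rightward, y downward, cm).
* `metadata.csv` — columns
  `trial_id,fish_id,age,swim_speed,displacement,trial_number` with
  `displacement` in {lateral, diagonal} and `trial_number` in {1, 2}.

Without these files the corresponding acceptance tests fail at their
data-availability assertion; all other tests are self-contained.
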